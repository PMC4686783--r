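# protein dna twist (degrees)
# SYNTHETIC stand-in values: representative of the published scale's range
# and reverse-complement symmetric, but NOT the published compilation.
# Only the bundled base stack energy table reproduces published values.
AA	31.31
AC	37.08
AG	32.49
AT	36.86
CA	35.31
CC	33.97
CG	30.48
CT	32.49
GA	30.49
GC	33.99
GG	33.97
GT	37.08
TA	31.47
TC	30.49
TG	35.31
TT	31.31
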