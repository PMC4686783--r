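# b dna (degrees)
# SYNTHETIC stand-in values: representative of the published scale's range
# and reverse-complement symmetric, but NOT the published compilation.
# Only the bundled base stack energy table reproduces published values.
AA	34.36
AC	36.02
AG	27.82
AT	31.03
CA	27.11
CC	35.37
CG	34.03
CT	27.82
GA	30.34
GC	37.67
GG	35.37
GT	36.02
TA	38.09
TC	30.34
TG	27.11
TT	34.36
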