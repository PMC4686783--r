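# dna denaturation (degrees C)
# SYNTHETIC stand-in values: representative of the published scale's range
# and reverse-complement symmetric, but NOT the published compilation.
# Only the bundled base stack energy table reproduces published values.
AA	109.92
AC	71.60
AG	93.30
AT	105.16
CA	89.82
CC	93.02
CG	107.69
CT	93.30
GA	89.45
GC	95.14
GG	93.02
GT	71.60
TA	101.36
TC	89.45
TG	89.82
TT	109.92
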