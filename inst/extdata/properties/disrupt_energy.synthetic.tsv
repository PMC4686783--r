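# disrupt energy (kcal/mole)
# SYNTHETIC stand-in values: representative of the published scale's range
# and reverse-complement symmetric, but NOT the published compilation.
# Only the bundled base stack energy table reproduces published values.
AA	3.05
AC	2.59
AG	1.73
AT	2.71
CA	2.99
CC	2.80
CG	1.97
CT	1.73
GA	2.57
GC	2.79
GG	2.80
GT	2.59
TA	2.16
TC	2.57
TG	2.99
TT	3.05
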