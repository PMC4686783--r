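# z dna (kcal/mole)
# SYNTHETIC stand-in values: representative of the published scale's range
# and reverse-complement symmetric, but NOT the published compilation.
# Only the bundled base stack energy table reproduces published values.
AA	0.79
AC	2.49
AG	5.49
AT	2.77
CA	3.83
CC	0.97
CG	5.08
CT	5.49
GA	2.51
GC	1.07
GG	0.97
GT	2.49
TA	5.02
TC	2.51
TG	3.83
TT	0.79
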