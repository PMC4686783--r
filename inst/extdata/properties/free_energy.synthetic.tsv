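# free energy (kcal/mole)
# SYNTHETIC stand-in values: representative of the published scale's range
# and reverse-complement symmetric, but NOT the published compilation.
# Only the bundled base stack energy table reproduces published values.
AA	-1.73
AC	-1.15
AG	-3.03
AT	-1.58
CA	-1.95
CC	-2.45
CG	-3.36
CT	-3.03
GA	-1.92
GC	-1.10
GG	-2.45
GT	-1.15
TA	-1.56
TC	-1.92
TG	-1.95
TT	-1.73
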