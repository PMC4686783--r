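# a philicity (a.u.)
# SYNTHETIC stand-in values: representative of the published scale's range
# and reverse-complement symmetric, but NOT the published compilation.
# Only the bundled base stack energy table reproduces published values.
AA	0.70
AC	-0.01
AG	1.06
AT	-0.12
CA	0.14
CC	0.81
CG	1.10
CT	1.06
GA	0.69
GC	0.12
GG	0.81
GT	-0.01
TA	0.43
TC	0.69
TG	0.14
TT	0.70
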