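# propeller twist (degrees)
# SYNTHETIC stand-in values: representative of the published scale's range
# and reverse-complement symmetric, but NOT the published compilation.
# Only the bundled base stack energy table reproduces published values.
AA	-13.49
AC	-9.24
AG	-9.13
AT	-17.87
CA	-9.94
CC	-16.90
CG	-15.40
CT	-9.13
GA	-16.01
GC	-9.21
GG	-16.90
GT	-9.24
TA	-16.11
TC	-16.01
TG	-9.94
TT	-13.49
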