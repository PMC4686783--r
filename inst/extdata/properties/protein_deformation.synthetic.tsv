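# protein deformation (degrees)
# SYNTHETIC stand-in values: representative of the published scale's range
# and reverse-complement symmetric, but NOT the published compilation.
# Only the bundled base stack energy table reproduces published values.
AA	7.00
AC	11.98
AG	3.68
AT	2.65
CA	2.21
CC	11.22
CG	10.55
CT	3.68
GA	3.19
GC	10.29
GG	11.22
GT	11.98
TA	11.34
TC	3.19
TG	2.21
TT	7.00
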