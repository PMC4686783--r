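# dna bending stiffness (nm)
# SYNTHETIC stand-in values: representative of the published scale's range
# and reverse-complement symmetric, but NOT the published compilation.
# Only the bundled base stack energy table reproduces published values.
AA	95.63
AC	23.00
AG	71.23
AT	90.92
CA	74.76
CC	115.42
CG	66.13
CT	71.23
GA	115.52
GC	56.73
GG	115.42
GT	23.00
TA	82.79
TC	115.52
TG	74.76
TT	95.63
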