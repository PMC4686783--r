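# bendability (a.u.)
# SYNTHETIC stand-in values: representative of the published scale's range
# and reverse-complement symmetric, but NOT the published compilation.
# Only the bundled base stack energy table reproduces published values.
AAA	-0.085
AAC	0.040
AAG	-0.215
AAT	0.120
ACA	0.155
ACC	0.064
ACG	-0.146
ACT	0.000
AGA	-0.150
AGC	-0.168
AGG	0.023
AGT	0.000
ATA	-0.007
ATC	-0.018
ATG	-0.138
ATT	0.120
CAA	-0.202
CAC	0.132
CAG	-0.279
CAT	-0.138
CCA	0.160
CCC	-0.148
CCG	-0.138
CCT	0.023
CGA	0.189
CGC	0.096
CGG	-0.138
CGT	-0.146
CTA	-0.138
CTC	0.103
CTG	-0.279
CTT	-0.215
GAA	0.127
GAC	-0.151
GAG	0.103
GAT	-0.018
GCA	0.091
GCC	-0.152
GCG	0.096
GCT	-0.168
GGA	0.087
GGC	-0.152
GGG	-0.148
GGT	0.064
GTA	0.060
GTC	-0.151
GTG	0.132
GTT	0.040
TAA	-0.004
TAC	0.060
TAG	-0.138
TAT	-0.007
TCA	0.015
TCC	0.087
TCG	0.189
TCT	-0.150
TGA	0.015
TGC	0.091
TGG	0.160
TGT	0.155
TTA	-0.004
TTC	0.127
TTG	-0.202
TTT	-0.085
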