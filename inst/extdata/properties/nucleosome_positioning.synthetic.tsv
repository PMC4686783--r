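# nucleosome positioning (percent)
# SYNTHETIC stand-in values: representative of the published scale's range
# and reverse-complement symmetric, but NOT the published compilation.
# Only the bundled base stack energy table reproduces published values.
AAA	38.3
AAC	-17.5
AAG	-8.6
AAT	-22.2
ACA	-19.0
ACC	17.5
ACG	15.5
ACT	-17.8
AGA	-2.8
AGC	28.3
AGG	9.0
AGT	-17.8
ATA	-12.8
ATC	36.3
ATG	9.0
ATT	-22.2
CAA	-14.1
CAC	13.8
CAG	43.8
CAT	9.0
CCA	-25.0
CCC	-16.9
CCG	10.0
CCT	9.0
CGA	38.5
CGC	8.1
CGG	10.0
CGT	15.5
CTA	30.7
CTC	27.6
CTG	43.8
CTT	-8.6
GAA	-8.9
GAC	-18.6
GAG	27.6
GAT	36.3
GCA	-21.9
GCC	40.0
GCG	8.1
GCT	28.3
GGA	13.7
GGC	40.0
GGG	-16.9
GGT	17.5
GTA	1.1
GTC	-18.6
GTG	13.8
GTT	-17.5
TAA	-20.5
TAC	1.1
TAG	30.7
TAT	-12.8
TCA	-2.3
TCC	13.7
TCG	38.5
TCT	-2.8
TGA	-2.3
TGC	-21.9
TGG	-25.0
TGT	-19.0
TTA	-20.5
TTC	-8.9
TTG	-14.1
TTT	38.3
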