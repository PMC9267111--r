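codon	copy_number
AAA	10
AAC	6
AAG	3
AAT	5
ACA	2
ACC	9
ACG	3
ACT	1
AGA	6
AGC	12
AGG	11
AGT	4
ATA	4
ATC	8
ATT	8
CAA	5
CAC	12
CAG	5
CAT	11
CCA	11
CCC	9
CCG	11
CCT	3
CGA	4
CGC	12
CGG	7
CGT	1
CTA	0
CTC	10
CTG	6
CTT	12
GAA	8
GAC	11
GAG	6
GAT	3
GCA	1
GCC	1
GCG	0
GCT	9
GGA	4
GGC	1
GGG	10
GGT	3
GTA	9
GTC	10
GTG	7
GTT	2
TAC	5
TAT	4
TCA	3
TCC	4
TCG	0
TCT	12
TGC	10
TGT	4
TTA	10
TTC	3
TTG	8
TTT	3
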