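name	consensus	category
AE-box	AGAAACAA	growth_development
ACE	GACACGTATG	growth_development
ATCT-motif	AATCTAATCC	growth_development
I-box	AGATAAGG	growth_development
Box 4	ATTAAT	growth_development
G-box	CACGTG	growth_development
GATA-motif	GATAGGG	growth_development
ARE	AAACCA	stress
WUN-motif	AAATTTCCT	stress
MBS	CAACTG	stress
LTR	CCGAAA	stress
W-box	TTGACC	stress
TC-rich repeats	GTTTTCTTAC	stress
ABRE	TACGTGTC	phytohormone
ERE	ATTTCAAA	phytohormone
CGTCA-motif	CGTCA	phytohormone
TGA-element	AACGAC	phytohormone
AuxRR-core	GGTCCAT	phytohormone
GARE-motif	TCTGTTG	phytohormone
P-box	CCTTTTG	phytohormone
TCA-element	CCATCTTTTT	phytohormone
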