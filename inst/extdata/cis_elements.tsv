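name	pattern	category
TATA-box	TATA	growth
CAAT-box	CCAAT	growth
G-box	CACGTG	growth
GT1-motif	GGTTAA	growth
I-box	GATAAG	growth
Box4	ATTAAT	growth
GATA-motif	GATAGGG	growth
CAT-box	GCCACT	growth
O2-site	GATGACATGG	growth
circadian	CAANNNNATC	growth
ABRE	ACGTGGC	hormone
CGTCA-motif	CGTCA	hormone
TGACG-motif	TGACG	hormone
ERE	ATTTCAAA	hormone
GARE-motif	TCTGTTG	hormone
P-box	CCTTTTG	hormone
TCA-element	CCATCTTTTT	hormone
TGA-element	AACGAC	hormone
AuxRR-core	GGTCCAT	hormone
MBS	CAACTG	stress
LTR	CCGAAA	stress
TC-rich	ATTTTCTTCA	stress
ARE	AAACCA	stress
WUN-motif	AAATTTCCT	stress
DRE	RCCGAC	stress
W-box	TTGACC	stress
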