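# columns: element, iupac, category, subcategory
# Editable IUPAC consensus dictionary of plant promoter cis-acting elements.
# Consensus strings are concise literature-style stand-ins, not proprietary
# position-weight matrices; absolute counts on real genomes will differ from
# matrix-based scanners.
element	iupac	category	subcategory
CGTCA-motif	CGTCA	phytohormone	MeJA
TGACG-motif	TGACG	phytohormone	MeJA
TCA-element	CCATCTTTTT	phytohormone	SA
SARE	TTCGACCATCTT	phytohormone	SA
ABRE	TACGTG	phytohormone	ABA
motif-IIb	CCGCCGCGCT	phytohormone	ABA
GARE-motif	TCTGTTG	phytohormone	GA
TATC-box	TATCCCA	phytohormone	GA
P-box	CCTTTTG	phytohormone	GA
AuxRR-core	GGTCCAT	phytohormone	IAA
TGA-element	AACGAC	phytohormone	IAA
ERE	ATTTCAAA	phytohormone	ethylene
HSE	AAAAAATTTC	stress	heat
TC-rich_repeats	ATTTTCTTCA	stress	defense
ARE	AAACCA	stress	anaerobic
GC-motif	CCCCCG	stress	anoxia
MBS	CAACTG	stress	drought
LTR	CCGAAA	stress	low-temperature
WUN-motif	AAATTTCCT	stress	wound
Skn-1_motif	GTCAT	development	endosperm
GCN4_motif	TGAGTCA	development	endosperm
CCGTCC-box	CCGTCC	development	meristem
circadian	CAANNNNATC	development	circadian
G-box	CACGTG	light	light
GAG-motif	AGAGAGT	light	light
GT1-motif	GGTTAA	light	light
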