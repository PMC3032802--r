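gene	half1	half2	spacer	repeat_name	class_family
GDF15	CATCTTGCCC	AGACTTGTCT	0	FLAM_C	SINE/Alu
BCL2L14	AGCCAAGGCT	GGTCTTGAAC	0	AluJr/Jo	SINE/Alu
CASP10_RE1	GGGCATGGTG	GGACATGCCT	0	AluJo/Jr	SINE/Alu
CASP10_RE2	GGGCATGGTG	GCACATGCCT	0	AluSp	SINE/Alu
BID	GGGCATGATG	GTGCATGCCT	0	AluSg	SINE/Alu
TSC2_RE1	GGGCATGGTG	GCACATGCCT	0	AluSg	SINE/Alu
EphA2	AGACATGCCT	CAACATGGTG	3	AluSz	SINE/Alu
HTT	CGCCATGTTG	AGGCTGGTCT	3	AluSq2	SINE/Alu
CASP6	AGGCAAGGAG	AGACAAGTCT	4	AluJr	SINE/Alu
BNIP3L	AAGCTAGTCT	GCGCATGCCT	5	AluJo/Jr	SINE/Alu
AIFM2_RE1	AGACCAGCCT	TAGCGAGACC	8	AluJo	SINE/Alu
AIFM2_RE2	GGGCATGGCC	GCTCATGCCT	10	AluJo	SINE/Alu
TSC2_RE2	AGGCTAGTCT	TGACGTGACC	13	AluJb	SINE/Alu
CCNK	AAACTAGCTT	AGACATGCTG	2	MIRb	SINE/MIR
CASP10_RE3	AAACTTGCTG	AATCTTGGCT	5	MIR	SINE/MIR
CTSD	AACCTTGGTT	TGCAAGAGGC	0	MER4D	LTR/ERV1
MMP2	AGACAAGCCT	GAACTTGTCT	0	LTR88b	LTR/Gypsy
SCN3B	TGACTTGCTC	TGCCTTGCCT	0	THE1B	LTR/ERVL-MaLR
TP53INP1	GAACTTGGGG	GAACATGTTT	0	MER21B	LTR/ERVL
TRIM22	TGACATGTCT	AGGCATGTAG	0	LTR10D	LTR/ERV1
CRYZ	CTGCAAGTCC	AAACCTGTTT	3	THE1B	LTR/ERVL-MaLR
PLK2	GGTCATGATT	TAACTTGCCT	3	MER34C	LTR/ERV1
COL18A1	TGACATGTGT	GAGCATGTAT	0	(TG)n	Simple_repeat
SCARA3	GGGCAAGCCC	AGACAAGTTG	0	MER81	DNA/hAT-Blackjac
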