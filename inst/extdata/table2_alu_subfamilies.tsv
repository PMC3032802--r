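subfamily	n_elements	n_motifs	S0	S3	S8	S14
FLAM-A	18264	5484	633	233	2080	1057
FLAM-C	35888	14083	1786	804	5036	3923
AluJo	137954	75938	13745	4424	20989	14007
AluJb	126856	62528	12542	11954	4297	9560
AluSx	333710	129530	32361	42879	8104	16192
AluSq	93874	30593	7253	12164	409	4445
AluSg	84797	30561	9593	6280	3608	3136
AluSp	50857	21429	13340	1904	127	2036
AluSc	43135	6884	2945	864	293	92
AluSg1	6130	4429	3570	72	186	200
AluY	139813	12488	1753	512	2542	360
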