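# Per-chromosome summary of the curated porcine immunome annotation:
# gene models, known genes confirmed, transcripts (total, protein-coding,
# complete protein-coding), predicted genes found to be pseudogenes, and
# transcripts annotated without same-organism sequence support.
chromosome	genes	known_genes	transcripts	protein_coding	complete_protein_coding	pseudogenes	non_organism_supported
1	103	78	218	179	120	9	65
2	102	83	292	220	122	1	86
3	74	59	167	130	60	0	38
4	186	125	452	354	222	5	119
5	72	61	174	140	85	0	47
6	90	67	220	176	97	2	81
7	76	66	163	122	92	1	37
8	45	34	102	84	39	0	23
9	62	45	132	106	53	1	38
10	21	19	84	68	32	0	20
11	9	9	13	11	8	0	3
12	105	82	221	181	95	4	68
13	68	52	173	139	69	0	67
14	84	63	265	200	100	2	103
15	38	31	100	76	38	1	39
16	23	17	58	45	17	0	23
17	39	34	79	66	39	0	18
18	14	11	19	17	8	0	3
X	158	52	540	462	258	0	294
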