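# Immune gene family sizes per species: functional gene counts, with
# pseudogene counts in the *_pseudo columns (0 where none reported).
# The cow beta defensin count is approximate (reported as ~106).
# Subfamily rows overlap their "(inclusive)" parents; filter before
# tallying if each gene should count once.
family	human	mouse	cow	pig	human_pseudo	mouse_pseudo	cow_pseudo	pig_pseudo
ADP-ribosyltransferase/VIP2 SF	4	5	9	4	0	1	0	0
Beta Defensin SF	39	51	106	34	9	1	7	2
BPI SF	12	16	18	14	2	0	0	2
C-type Lysozyme/LYZ1 SF	9	9	16	7	0	0	0	0
Cathelicidin SF	1	1	10	10	0	0	0	0
CCL Chemokine	28	39	22	21	1	5	0	0
CD1 SF	5	2	15	4	0	0	2	1
CD163/WC1 SF	3	4	15	4	0	0	0	0
CLECT SF (inclusive)	85	126	89	76	3	6	0	0
CLECT SF, AGP and DCR Subfamily	16	24	14	13	0	1	0	0
CLECT SF, Collectin Subfamily	7	7	10	7	2	0	0	0
CLECT SF, NK Cell Receptor Subfamily	24	57	31	23	1	5	0	0
CLECT SF, Reg Subfamily	5	7	3	3	0	0	0	0
Cytidine Deaminase-like SF	11	5	6	5	0	0	0	0
GH18 Chitinase Like SF	6	9	8	7	1	1	0	0
Granzyme/MC Tryptase/SP SF	17	26	22	18	1	0	0	0
Immunity Related GTP-ase SF	3	19	4	4	2	4	0	0
NLR and Pyrin SF	31	43	23	25	4	8	0	0
Resistin SF	2	4	1	2	0	0	0	0
RNase A Family	14	22	16	13	0	6	1	1
S100 SF	21	17	19	20	0	1	0	0
SAA SF	4	5	6	6	1	0	0	0
SLAM SF	9	9	12	11	1	0	0	0
Toll Like Receptor	10	12	10	10	3	1	0	2
TRIM E3 Up Ligase SF, TRIM5 Subfamily	4	10	5	3	0	1	0	0
Type I Interferon (inclusive)	17	25	51	39	12	2	13	16
Type I Interferon, Alpha Subfamily	13	13	19	18	4	1	3	9
Type I Interferon, Beta Subfamily	1	1	8	1	0	0	1	0
Type I Interferon, Delta Subfamily	0	0	0	11	0	0	0	2
Type I Interferon, Epsilon Subfamily	1	1	0	1	0	0	0	0
Type I Interferon, Kappa Subfamily	1	1	1	1	0	0	0	0
Type I Interferon, Omega Subfamily	1	0	19	7	8	0	7	5
Type I Interferon, Tau Subfamily	0	0	4	0	0	0	2	0
Type I Interferon, Zeta Subfamily	0	9	0	0	0	1	0	0
ULBP SF	6	2	12	7	0	0	0	0
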