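# SYNTHETIC exclusive Venn-region counts for the 597-gene four-species
# ortholog comparison. Only marginal queries of the real table are
# published (184 genes with 1:1 orthology in all four species; 18 genes in
# pig and cow but not human or mouse; 42 in human and pig but not mouse;
# 14 in human and mouse but not pig; 7 in mouse and pig but not human;
# 174 mouse-only; 87 cow-only). This file is one consistent completion of
# those marginals into the 15 exclusive regions; regions not pinned down
# by a published number are an arbitrary but fixed split.
# 'present' lists the species carrying the gene; all others lack it.
present	count
human	30
mouse	174
cow	87
pig	16
human+mouse	6
human+cow	10
human+pig	20
mouse+cow	10
mouse+pig	3
cow+pig	18
human+mouse+cow	8
human+mouse+pig	5
human+cow+pig	22
mouse+cow+pig	4
human+mouse+cow+pig	184
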