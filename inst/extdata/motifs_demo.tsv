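motif_id	name	consensus
tcf4	TCF4	CAGGTG,CACCTG
prrx1	PRRX1	TAATT
tcf12	TCF12	TGTTTRCW
foxo1	FOXO1	WTGTTTAC
nfib	NFIB	STTYGC
nfkb	NF-kB	GGGRNNYYCC
ap1	AP-1	TGASTCA
cebpg	CEBPG	TTGCGCAA
irf	IRF	AANTGAAA
stat3	STAT3	TTCNNNGAA
myc	MYC	CACGTG
usf1	USF1	CACGTGAC
srf	SRF	CCWWWWWWGG
mef2	MEF2	CTAWWWWTAG
creb1	CREB1	TGACGTCA
sp1	SP1	GGGGCGGGG
klf4	KLF4	GGGGTGGGG
gata3	GATA3	WGATAR
runx1	RUNX1	TGTGGT
ets1	ETS1	MGGAW
elk1	ELK1	CCGGAAGT
nfat	NFAT	GGAAA
oct1	POU2F1	ATGCAAAT
sox9	SOX9	AACAAT
pax6	PAX6	TTCACGC
hnf4a	HNF4A	CAAAGTCCA
rara	RARA	AGGTCA
p53	TP53	RRRCWWGYYY
yy1	YY1	CCATNTT
ctcf	CTCF	CCCTC
tead1	TEAD1	GGAATG
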