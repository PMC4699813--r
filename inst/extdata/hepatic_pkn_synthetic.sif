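# Curated example of an IL-6 hepatic signalling + DMET gene-regulation PKN.
# SYNTHETIC transcription: hand-assembled to approximate the published
# figure-level topology of such networks; not a verbatim copy of any
# supplementary file.
IL6	1	gp130
gp130	1	JAK1
JAK1	1	STAT3
gp130	1	SHP2
SHP2	1	RAS
RAS	1	RAF1
RAF1	1	MEK
MEK	1	ERK
SHP2	1	PI3K
PI3K	1	AKT
AKT	1	IKK
IKK	1	NFKB
ERK	-1	RXRNR
NFKB	-1	RXRNR
ERK	-1	GR
NFKB	-1	AHR
STAT3	1	SOCS3
STAT3	1	SOCS1
SOCS3	-1	JAK1
SOCS1	-1	JAK1
STAT3	1	CRP
STAT3	1	SAA1
NFKB	1	CRP
RXRNR	1	CYP3A4
RXRNR	1	CYP2C8
RXRNR	1	CYP2C9
RXRNR	1	CYP2C19
RXRNR	1	CYP2B6
RXRNR	1	CYP1A2
RXRNR	1	CYP2A6
RXRNR	1	CYP2D6
RXRNR	1	ABCB1
RXRNR	1	ABCC2
RXRNR	1	ABCG2
RXRNR	1	SLCO1B1
RXRNR	1	SLC10A1
RXRNR	1	UGT1A1
RXRNR	1	UGT2B7
RXRNR	1	GSTA1
RXRNR	1	SULT1A1
RXRNR	1	NAT1
RXRNR	1	NAT2
HNF1A	1	ALB
HNF4A	1	TTR
HNF1A	1	CYP2E1
GR	1	TSC22D3
GR	1	PER1
NFKB	-1	PPARA
AHR	1	CYP1A1
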