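G1S	replication-phase program	MCM5	PCNA	TYMS	FEN1	MCM2	MCM4	RRM1	UNG	GINS2	MCM6	CDCA7	DTL	PRIM1	UHRF1	HELLS	RFC2	RPA2	NASP	RAD51AP1	GMNN
G2M	mitosis-phase program	CDK1	TOP2A	UBE2C	BIRC5	TPX2	CCNB1	CCNB2	AURKA	AURKB	BUB1	KIF11	PLK1	CDC20	MKI67	CENPF	CENPA	CENPE	NUSAP1	CKS2	ANLN
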