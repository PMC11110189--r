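PPARG	myeloid PPARG regulon target genes	FTL	ACP5	GRN	ASAH1	FBP1	CTSS	APOE	GLUL	SLA	TXNIP	BRI3	CD68	MSR1	VSIG4	BHLHE41	ALDH2	ALOX5	CSTB	TMBIM1	CD52	LIPA	GPNMB	CPM
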