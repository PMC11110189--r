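T	canonical T-cell markers	CD3D	CD3E	CD2	TRAC	IL7R	CD7
B	canonical B-cell markers	CD79A	CD79B	MS4A1	CD19	IGHM
myeloid	canonical monocyte/macrophage markers	CD14	LYZ	AIF1	CSF1R	FCN1	TYROBP
epithelial	canonical epithelial markers	EPCAM	KRT8	KRT18	KRT19
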