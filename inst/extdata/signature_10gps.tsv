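# 10-pair MSI signature for right-sided colon cancer; pattern gene1 > gene2 votes MSI
# vote_threshold: 7
gene1	gene2
HNRNPL	CDC16
MTA2	VGF
CALR	SEC22B
RASL11A	CAB39L
LYG1	DHRS12
STRN3	TMEM192
HPSE	BCAS3
PRPF39	ATF6
CCRN4L	GRM8
AMFR	DUSP18
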