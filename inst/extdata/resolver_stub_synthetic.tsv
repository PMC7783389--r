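name	id	synonyms
gag-pol protein	SYN:P0001	gag-pol|gag-pol polyprotein
pol peptide	SYN:P0002	pol protein
reverse transcriptase	SYN:P0003	rt|hiv-1 rt
samhd1	SYN:P0004	samhd1 protein|sam domain and hd domain-containing protein 1
hsp90	SYN:P0005	heat shock protein 90
integrase	SYN:P0006	hiv integrase
protease	SYN:P0007	hiv-1 protease
dasatinib	SYN:C0001	bms-354825
tanespimycin	SYN:C0002	17-aag
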