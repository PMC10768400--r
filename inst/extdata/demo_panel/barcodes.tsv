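role	name	sequence
F	F01	GACGTTCT
F	F02	CGAACGTA
F	F03	AAGGTCAG
F	F04	TGCACCGT
F	F05	GAAGTATA
F	F06	CGGACTCG
F	F07	TTTACCAC
F	F08	GCGCTCGG
F	F09	CTCTCATT
F	F10	ACTCTTCC
R	R01	TTGTCGGG
R	R02	ACGCGATG
R	R03	TTATATAA
R	R04	GCTCGGGC
R	R05	ACAAGACA
R	R06	TATGAAGC
R	R07	GGCAGTAT
R	R08	CAAGAGCA
R	R09	CAGGATTG
R	R10	GGGTGAAG
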