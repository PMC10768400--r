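sample_id	fwd_barcode	rev_barcode	island	species
BIJ001	GACGTTCT	TTGTCGGG	Bubaque	An. gambiae s.s.
BIJ002	CGAACGTA	TTGTCGGG	Tchedega	hybrid
BIJ003	AAGGTCAG	TTGTCGGG	Orangozinho	An. melas
BIJ004	TGCACCGT	TTGTCGGG	Soga	An. coluzzii
BIJ005	GAAGTATA	TTGTCGGG	Uno	An. gambiae s.s.
BIJ006	CGGACTCG	TTGTCGGG	Bubaque	hybrid
BIJ007	TTTACCAC	TTGTCGGG	Tchedega	An. gambiae s.s.
BIJ008	GCGCTCGG	TTGTCGGG	Orangozinho	hybrid
BIJ009	CTCTCATT	TTGTCGGG	Soga	An. gambiae s.s.
BIJ010	ACTCTTCC	TTGTCGGG	Uno	hybrid
BIJ011	GACGTTCT	ACGCGATG	Bubaque	An. melas
BIJ012	CGAACGTA	ACGCGATG	Tchedega	An. coluzzii
BIJ013	AAGGTCAG	ACGCGATG	Orangozinho	An. gambiae s.s.
BIJ014	TGCACCGT	ACGCGATG	Soga	hybrid
BIJ015	GAAGTATA	ACGCGATG	Uno	An. gambiae s.s.
BIJ016	CGGACTCG	ACGCGATG	Bubaque	hybrid
BIJ017	TTTACCAC	ACGCGATG	Tchedega	An. gambiae s.s.
BIJ018	GCGCTCGG	ACGCGATG	Orangozinho	hybrid
BIJ019	CTCTCATT	ACGCGATG	Soga	An. melas
BIJ020	ACTCTTCC	ACGCGATG	Uno	An. coluzzii
BIJ021	GACGTTCT	TTATATAA	Bubaque	An. gambiae s.s.
BIJ022	CGAACGTA	TTATATAA	Tchedega	hybrid
BIJ023	AAGGTCAG	TTATATAA	Orangozinho	An. gambiae s.s.
BIJ024	TGCACCGT	TTATATAA	Soga	hybrid
BIJ025	GAAGTATA	TTATATAA	Uno	An. gambiae s.s.
BIJ026	CGGACTCG	TTATATAA	Bubaque	hybrid
BIJ027	TTTACCAC	TTATATAA	Tchedega	An. melas
BIJ028	GCGCTCGG	TTATATAA	Orangozinho	An. coluzzii
BIJ029	CTCTCATT	TTATATAA	Soga	An. gambiae s.s.
BIJ030	ACTCTTCC	TTATATAA	Uno	hybrid
BIJ031	GACGTTCT	GCTCGGGC	Bubaque	An. gambiae s.s.
BIJ032	CGAACGTA	GCTCGGGC	Tchedega	hybrid
BIJ033	AAGGTCAG	GCTCGGGC	Orangozinho	An. gambiae s.s.
BIJ034	TGCACCGT	GCTCGGGC	Soga	hybrid
BIJ035	GAAGTATA	GCTCGGGC	Uno	An. melas
BIJ036	CGGACTCG	GCTCGGGC	Bubaque	An. coluzzii
BIJ037	TTTACCAC	GCTCGGGC	Tchedega	An. gambiae s.s.
BIJ038	GCGCTCGG	GCTCGGGC	Orangozinho	hybrid
BIJ039	CTCTCATT	GCTCGGGC	Soga	An. gambiae s.s.
BIJ040	ACTCTTCC	GCTCGGGC	Uno	hybrid
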