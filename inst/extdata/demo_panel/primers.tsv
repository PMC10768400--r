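amplicon	forward	reverse
vgsc-I	CAGCCCTCTGTCAATGGCTC	TATACAAGAAAGACCCCCGA
vgsc-II	GCTATTCATCATGCAGAGTC	CTGGAATTGAATACCGAATA
vgsc-III	TGTACCATGTCCTGCGCGTC	AGGCTAGACAAATAGTTGCC
vgsc-IV	ATAAGTGGGGCAATCGTTAA	TAGAGACAACCCGAGAGCGC
rdl	CACAACCCCAGGCAGGCTAA	CTGTACCCGCCTCAGCGTAC
gste2	GGGAGGTAAGTCTCGGTTAA	AGCCTCAGCCCACAGTCGCC
ace1	TTGTAAGAACTTAGTGCAAT	TCCAGCTTAGGCATGAAATC
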