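>An_gambiae_s_s__synthetic_IGS
ATGTACACGCCTTGCATCTCCAATCGTCATGTGTGCCCCTTCCTCGATGTTGAGGATGGC
ATCTGTTCATGAGTCATCGGCAATGATTAGCTAGGAGGGGTGCTCATCTTACGCTTGTTC
CCAATGCAGCCCTCTTGTCTGGGGGTACGGTCCAGAGCTTCGGACATCGCCACGCCGCGG
TCCTCGCGAAACGGTAACATGCTATTGCTGTACATTTAGACTTGGTTAGGAATAAGCCTG
ACTTGGGCAATAGTAACTAACTGGTCAAGAGTAGGCCTGTACTTGCGCAGGAACGACCAT
CTGCCTTTTGTAGTCGAAATACATCCTCGTGCTTCCCTATTAGTGCTAGGCGTAAGGCAG
ATTTCTGGCCCGTACGCAAACGTGCCGACCAAACCAGGGTTTCGTGATCGTGAAGGGTCT
GTAATTG
>An_coluzzii_synthetic_IGS
TCACAATGCCATTTGACATCCGCGTTCCAGGTGTGCCCCTTCCTCGATGTGCAGAGCCCC
CTGGCGGAAGTAGCGAAACGGTACCCGCCCGACCGATGTTCCCAGAGTCCACCGTGTCTG
CCAGCTGTAGTGACGGCAGCTGCCTCCCCAATGCCATCTAGGGCGGCGGTTTTCATGGGA
CTTTTCTGGACCTCCTCCTGACGTTACAGGGATACTAAGAGACGCCAGAATCACCGGATA
AGCATCTTAAACGGAGGCCGCAAGTAAAATATTGCCTGGCTGGATAAAATGCTACTTAGC
TTGTAAAACGATACCCATAAATGAATGAATTTAGCATAATGACTCGAGGGAGTAGGGTGA
TAGGATCATAGAAGTAAAAACGTGCCGACCAAACCAGCAGCCAACCAACGCATCCGCTGA
CCCGATG
>An_arabiensis_synthetic_IGS
GTTTGTCAAATGGCATTTTCCTCGCATGAGGTGTGCCCCTTCCTCGATGTCCAGCATCCC
CATCAGGTTGAACTGACGTGTGAATCGTGAGGGAGATCAATAAATAGCATTAAGTATTAG
GCACAATGGTAGCGAGCCGTAGATCGTAAGCCGGTCCATCTTTCTCTTGGGACCGCTTGC
TCCACCCCTTCACTAGCATCCAGTTAAGGGAACAAGATCAGCTGATCCTTGTACTCATTC
CTTCACTCAACCGCAAGGGAGATGGAAAGGGGGGTGCCCGCACATAAAAAGTGTACAGAT
ATTAGGATGGAGAAGGACACTTAGCTTTCGCTCCGTCTTAGCTACCTCACTC
>An_melas_synthetic_IGS
CCGCATGCTATGGTCTCGACGCGGGCGTTCGTGTGCCCCTTCCTCGATGTAAAGTGACAA
GAAATGGGGCCCACGCCCGGACATGGGCTGTTAATCTAACGTACTCCTGCTATTTGTCAT
GCATTCAAATCTGTTCAGTGAGTGGACATTGGTTCGGATGAATGATCAGACATCCTTTGT
CTTATATCATGTTGTCCAGTTTCTTCGCCGTATTGGCTAAGGCGTCGTCCCCCGAACCTT
GCCGCATTTACGGTCCGATGGCGGCAATCACGATCGTCCTACTCGTATCCGAGGTAGCTC
GAGTGATCTAAGACTTAGAACGTCTTTGCCCTCGCTTTCTCAGATGGAGTTCAACCTGCA
ACCGTTGATCGGCCTGATGGTTCTTGTTACTGCGAGAGTGCCCTTCTTAAAGGGAAGAAG
CCCTTTCTGTCCACGCGACGCACCATCAAGGGAGTGGGTTGGTCATATCATTTATAACCT
GCTGCACGACGGGTA
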