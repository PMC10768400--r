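>vgsc-I
CAGCCCTCTGTCAATGGCTCGCGCTAAGTCTAACTAGACGAAAATAAACACCAGACCGGT
CTGAGGACCCTCGACTTTGCGCGGCACTGAGTGTCTTGCTCTGCGTCGTGGCCACTGTTT
AAATCGTGGTTAAGGGCTAGAATTGCGGTCCAATGCGTGCTCCAAATCAGTTCGGCAATA
AATCGCGGTGCCAAGTAAAAAACGGCATGGGGGGGTGGCCTATCTAAAGTAACAGTAGAA
CGAGATTGACGGGAGGGAAGTGGAGCATTGTCGCACCGTGCAGCTGGTCAGCTACACATT
TTATGATAAAGTTTGCTAGTGCAGCATGGCTCGTTGACCTTCCAGGCCGACAATTCACTA
GGTTCGTCTTTTACAAGTGGACACCACGCGGTTATCTCATGTTGATACGTATCACACAGC
GCGACATGACTAGGGGCAACCTGCGTCTGCTCGGGGGTCTTTCTTGTATA
>vgsc-II
GCTATTCATCATGCAGAGTCCTAAAGAGTCCTGTTCAGACGTTCTGGCCTTAATATGCGA
GAGCCTTCGGCGACAACGACGTGGGACCTTTGTCCGAAGTGATAACCAGGGGTACGCGAA
ACATAGCACAACCTGAAGGAAGAAAGTGCCGTGCATTTTGAGCTGGCACCAGACGATGGA
GTCGGTGTGCCCAATACTCCTTGTGTGTGTGACAGTATCCGCGAGCATTTCATGCGCTTA
CTTGCAACACAGGTTGGCCTTTTGTCTGGCAGAGGCGCGATGACATCTGTCGCCTTCTCG
TGCATACAGCATGATAGCTCTCATAGGCAAGAGGGATGTGTATGGAACAGTGATGAAATA
GGTGCGTGAGAAGGTTCGCCAGCAGGGCAGGTAGATCTGATTTGTGTTCTTGAAGGTAAA
TAACTACCAGGTTAGGCACAAGTTTTTTCCTATTCGGTATTCAATTCCAG
>vgsc-III
TGTACCATGTCCTGCGCGTCAGCGGATTTAGCTATCGAGCTCTTAAAGGCCAAACCAAGC
AATGCAGCTTTTGGTCTCGATCGGAAATCTCGAGCACTTTTCTTCGCCATAGCTCCACAC
TCAGAGATAGAGGATCTGCGAACAGTACTCACATCGCTGGCGGGAATATACCGACTCAAC
TGGGTCCTAAGCATTGGTGCGGAACCAGGAGCAGGAGACCCGCTATTGCGTTGCACCAAT
GTGGGAGACCCGTGATCGGTTCTCCGTCAAGGGTCATACTAATCCATTGGAGGTCTCTAG
TCGACATCATCGAATTGCAGTATTTCAATTGTCCAGGAAGATCCTTAAGGAAATATATTC
GCAGCGTTCCCCTTTGCGAAAGTTTAAAGTGTCAAGAATGCAGTTGTCAGGGTAAAAATG
ATGGCATATTCCTGCTCATGAAACCACTCCGGCAACTATTTGTCTAGCCT
>vgsc-IV
ATAAGTGGGGCAATCGTTAATCTCTGTTTAATAGTGCTCACATCAGCTGTTAACGTCTGG
CCTTCCCCTACAAAGCCAAAAGGGCCACTGTGGACTGCATCGATTACGCGGGTTCAATAC
TGAGTGTGTACGTGATGCAAAGGCTACACCCAGAGATGGTGGTCTGGAAATTATCTAGTC
CCAGTTCAGTGCAGATATTCCCGCCTGGGCTTAAGAACCAATAGTCTCGGCTCATAGAGT
GACGTCTTGGTGACCTATAAATATGGGATTTTATAAATACGGCGTCCGGGTGAAAGCTGC
GATCGACCGATGTAAGGGCAAAGAGATAGGGTCAGAAGGCAGGATCATCGCGATGTCCAC
GCACCGGACTGGCCGCCCTTAGCCAGCTCTCGTTAAGGCAGACAGCGGAGGCGACGGACC
GTAGAACATCCATACACCCCTTCGTATTCCGCGCTCTCGGGTTGTCTCTA
>rdl
CACAACCCCAGGCAGGCTAAGACTAAGTGTCGGTTGTCTTTGGGCCCAGCCATGTCTGGT
TCAACGTAACTGGCGGTTGAAAGGTCTTCGACTGCCTACTGGCGCGGACGGGCTCTTGAC
GTACTGGACGCTCTACACGGACTGCAGATCTTAGAGGGCAATAACAATCTAGTGAGGAGG
TAGTAAAAAGTCAGCACGACAAAGCCCGCGTATGCAGGCATATCGTTAGCAGAGGATAGT
TAAGCGAGTGCTAATAAACCAAACATCTCGCAGATACGTTTATGAGTGTCCGGGGCCTAC
GTAGAAAGACAGGCCCGTGCAGTACGGTCGCGCTCGTATAAAAGAAATAGGAATAGCAAG
TCCCCGGAGGTATGGACCGTCTGAAATTTACGACAGAATCAACACCCATCCCCAGATAAT
TGTTGATTGAGCAGCCGCGTGGGAACCTCCGTACGCTGAGGCGGGTACAG
>gste2
GGGAGGTAAGTCTCGGTTAACTTGCGGAGTTATAGTCTGTCCGACTTCTTTTTTATACGA
AGACATGACGCTAGCTCGATCGGGACGCGCGCCTCTAGCTTTCCTTGCAGGGTTCTGAAC
CAACGGCTAAGAGACTTACCATATTCGTCCACGACCAGACCTCTTCTTGTCCCCTCATAT
ATTTAGAATCACACCCGGCCTTGGATTGCGTCGACAATGAGCGAATGGCCCGTCACCTTA
TCTTGGGCTGTTCTACTCGGAGCACTCGTCGAACCAGCTGCGGGCAGTTAAGTTACCTGA
GGCGGAGGGGGCACCAGATTCTCCACCGACCCAGTACGCTCTGCAGTGTGTGATTGCTAG
TACAGGGCGCACCTCTCACGCTATCGCGAAAAGAACGGATCAACCAATTAAAACACCTGG
ACCACCCGGCCTATACGCAGCATGGGTTACGGCGACTGTGGGCTGAGGCT
>ace1
TTGTAAGAACTTAGTGCAATAGCAGAGAGGCGCGGTTGCGTACGGCGGTGCTTACCGAGC
GGCCAACAGTTAGTAATCGTCAGGGCGTAAACGCCGCCGGCAGCCCGGAGGGCTCGCTAC
CAAAGGAGTCGCTGGCGAATACCACGTGGCCATGGTGGACGAGGCTCTAGTTTATATCTT
GGCTCATCCAACAAGTTCGGGGTTACCCCTATGGCCCAGTCCATTGGGGCTCGAAGATTC
TCGTTTTAAGATCGCCTGTGAAGGTAACGTTCGCATAAGAGAATTTTCTTTGCAGACTAA
GAGTTAATATTCTGGACCAAGGACTAACTACAACGGATGTCGAAACTGCGCAAGCCCGCT
TACTGGGGTACGGCAGATACCACGGAGCACCCGGATAAGCTCAGAAATGAAATCCTGTCC
CATCTCTGCCTGACAGGGCAATATAGCTACGATTTCATGCCTAAGCTGGA
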