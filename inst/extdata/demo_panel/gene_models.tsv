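amplicon	gene	strand	exon_start	exon_end	phase	codon_offset
vgsc-I	vgsc	+	2391102	2391521	0	359
vgsc-II	vgsc	+	2422443	2422862	0	925
vgsc-III	vgsc	+	2429538	2429957	0	1500
vgsc-IV	vgsc	+	2430409	2430828	0	1740
rdl	rdl	+	25429037	25429456	0	229
gste2	gste2	-	28597700	28598119	0	99
ace1	ace1	+	3491730	3491909	0	240
ace1	ace1	+	3491970	3492149	0	240
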