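id	gene	chrom	start
vgsc-I	vgsc	2L	2391072
vgsc-II	vgsc	2L	2422413
vgsc-III	vgsc	2L	2429508
vgsc-IV	vgsc	2L	2430379
rdl	rdl	2L	25429007
gste2	gste2	3R	28597670
ace1	ace1	2R	3491700
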