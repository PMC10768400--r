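gene	amplicon	chrom	pos	ref	alt	label	association
vgsc	vgsc-I	2L	2391228	G	T	V402L	pyrethroid (candidate)
vgsc	vgsc-I	2L	2391420	G	C	D466H	pyrethroid (candidate)
vgsc	vgsc-II	2L	2422652	A	T	L995F	pyrethroid/DDT (kdr-west)
vgsc	vgsc-II	2L	2422651	T	C	L995S	pyrethroid/DDT (kdr-east)
vgsc	vgsc-III	2L	2429617	T	C	I1527T	pyrethroid (candidate)
vgsc	vgsc-III	2L	2429745	A	T	N1570Y	pyrethroid (with L995F)
vgsc	vgsc-IV	2L	2430424	G	T	A1746S	pyrethroid (candidate)
vgsc	vgsc-IV	2L	2430808	C	T	P1874S	pyrethroid (candidate)
rdl	rdl	2L	25429236	C	G	A296G	dieldrin
rdl	rdl	2L	25429328	G	A	V327I	dieldrin (candidate)
ace1	ace1	2R	3491847	G	A	G280S	carbamate/organophosphate
gste2	gste2	3R	28598076	A	G	I114T	pyrethroid
gste2	gste2	3R	28598062	G	A	L119F	pyrethroid/DDT
gste2	gste2	3R	28598062	G	C	L119V	DDT
gste2	gste2	3R	28598059	A	G	F120L	DDT
gste2	gste2	3R	28597956	G	C	T154S	DDT (candidate)
gste2	gste2	3R	28597896	G	A	P174L	DDT (candidate)
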