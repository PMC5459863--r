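rule	h2	h5	le1	le2	spacing	substrate	tier
pip_water	F	H	T	R	*	water	1
pip_h2o2	F	H	T	R	*	hydrogen_peroxide	2
tip_water	H|N	I|M|V	A|G	V|R|C	*	water	1
tip_urea	H|N	I|M|V	A|G	V|R|C	*	urea	2
tip_h2o2	H|N	I|M|V	A|G	V|R|C	*	hydrogen_peroxide	2
tip2_ammonia	H	I	G	R	*	ammonia	2
nip1_glycerol	W	V|I	A	R	*	glycerol	1
nip1_water	W	V|I	A	R	*	water	2
nip2_boric	A	I|V	G|A	R	*	boric_acid	1
nip2_urea	A	I|V	G|A	R	*	urea	2
nip3_silicic	G	S	G	R	108	silicic_acid	1
sip_water	S|T|V	H|V|F	G|P	A|I	*	water	2
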