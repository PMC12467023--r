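gene_id	species_id	tissue	m_fpkm	f_fpkm
LOC100169004	Apis	whole body	51.345	168.215
AALB006416	Aalb	carcass	104.623	122.974
AgaP_AGAP000308	Agam	carcass	63.344	193.023
Aste1435_g	Aste	whole body	27.62	73.823
KWMTBOMO04424	Bmor	head	63.89	228.915
LOC4815668	Dpse	whole body	7.62	29.735
LOC663373	Tcas	gonad	59.295	1.458
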