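gene_id	species_id	tissue	m_fpkm	f_fpkm
LOC103309830	Apis	whole body	1.72	9.645
KWMTBOMO13951	Bmor	gonad	7.865	8.465
LOC6901163	Dpse	whole body	3.41	8.165
LOC103314026	Tcas	gonad	12.053	3.96
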