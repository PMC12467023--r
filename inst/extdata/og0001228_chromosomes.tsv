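gene_id	chromosome_class
LOC100169004	autosome
AALB006416	X
AgaP_AGAP000308	X
Aste1435_g	X
KWMTBOMO04424	autosome
LOC4815668	X
LOC663373	autosome
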