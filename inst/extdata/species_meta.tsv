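species_id	order_name	sex_system	display_name
Apis	Hemiptera	XO	Acyrthosiphon pisum
Tcas	Coleoptera	XY	Tribolium castaneum
Bmor	Lepidoptera	ZW	Bombyx mori
Dple	Lepidoptera	ZW	Danaus plexippus
Aaeg	Diptera	XY	Aedes aegypti
Aalb	Diptera	XY	Anopheles albimanus
Agam	Diptera	XY	Anopheles gambiae
Aste	Diptera	XY	Anopheles stephensi
Dmel	Diptera	XY	Drosophila melanogaster
Dpse	Diptera	XY	Drosophila pseudoobscura
Dsim	Diptera	XY	Drosophila simulans
Dvir	Diptera	XY	Drosophila virilis
Dyak	Diptera	XY	Drosophila yakuba
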