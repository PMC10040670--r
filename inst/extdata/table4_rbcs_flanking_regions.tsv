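genus	species	region1	region2	ptype
Echinochloa	Echinochloa crus-galli	PFQGLKSTAGL	CMQIWPVENN	C4
Saccharum	Saccharum hybrid	PFQGLKSTASL	CMQVWPAYGN	C4
Sorghum	Sorghum bicolor	PFQGLKSTATL	CMQVWPAYGN	C4
Setaria	Setaria italica	PFQGLKSTA(R/G)L	CMQVWP(A/I)EG(N/G)	C4
Miscanthus	Miscanthus x giganteus	PFQGLKSTASL	CMQVWPAYGN	C4
Panicum	Panicum hallii	PFQGLKSAAGL	CMQVWPTENN	C4
Zea	Zea mays	PFQGLKSTASL	CMQVWPAYGN	C4
Oryza	Oryza barthii	PFQGLKSTAG(L/M)	CMQVWPIEGI	C3
Oryza	Oryza brachyantha	PFQGLKSTAGM	CMQVWPIEGI	C3
Oryza	Oryza glaberrima	PFQGLKSTAG(L/M)	CMQVWPIEGI	C3
Oryza	Oryza glumipatula	PFQGLKSTAG(L/M)	CMQVWPIEGI	C3
Oryza	Oryza meridionalis	PFQGLKSTAG(L/M)	CMQVWPIEGI	C3
Oryza	Oryza nivara	PFQGLKSTAG(L/M)	CMQVWPIEGI	C3
Oryza	Oryza punctata	PFQGLKSTA(G/D)(L/M)	CMQVWP(V/I)(D/E)G(K)I	C3
Oryza	Oryza rufipogon	PFQGLKSTAG(L/M)	CMQVWPIEGI	C3
Oryza	Oryza sativa	PFQGLKSTAG(L/M)	CMQVWP(V/I)(D/E)G(K)I	C3
Brachypodium	Brachypodium distachyon	PFQGLKSTAGL	(S/C)MQVWPIEGI	C3
Secale	Secale cereale	PFQGLKSTAGL	CMQVWPIEGI	C3
Leersia	Leersia perrieri	PFQGLKSTAG(L/M)	CMQVWPIEGI	C3
Bromus	Bromus catharticus	PFQGLKSTAGL	CMQVWPIEGI	C3
Phleum	Phleum pratense	PFQGLKSTAGL	CMQVWPIEGI	C3
Aegilops	Aegilops bicornis	PFQGLKST(A/G)GL	CMQVWPIEGI	C3
Aegilops	Aegilops longissima	PFQGLKSTAGL	CMQVWPIEGI	C3
Aegilops	Aegilops searsii	PFQGLKSTAGL	CMQVWPIEGI	C3
Aegilops	Aegilops sharonensis	PFQGLKSTAGL	CMQVWPIEGI	C3
Aegilops	Aegilops speltoides	PFQGLKSTAGL	CMQVWPIEGI	C3
Aegilops	Aegilops tauschii	PFQGLKSTAGL	CMQVWPIEGI	C3
Triticum	Triticum aestivum	PFQGLKSTAGL	CMQVWPIEGI	C3
Triticum	Triticum dicoccoides	PFQGLKSTAGL	CMQVWPIEGI	C3
Triticum	Triticum timopheevii	PFQGLKSTAGL	CMQVWPIEGI	C3
Triticum	Triticum turgidum subsp. durum	PFQGLKSTDGL	CMQVWPIEGI	C3
Triticum	Triticum urartu	PFQGLKST(A/T)G(L/M)	CMQVWPIEGI	C3
Elytrigia	Thinopyrum intermedium	PFQGLKSTAGL	CMQVWPIEGI	C3
Avena	Avena agadiriana	PFQGLKSTAGL	CMQVWPIEGI	C3
Avena	Avena clauda	PFQGLKSTAGL	CMQVWPIEGI	C3
Avena	Avena maroccana	PFQGLKSTAGL	CMQVWPIEGI	C3
Avena	Avena sativa	PFQGLKSTAGL	CMQVWPIEGI	C3
Avena	Avena sterilis subsp. ludoviciana	PFQGLKSTAGL	CMQVWPIEGI	C3
Avena	Avena strigosa	PFQGLKSTAGL	CMQVWPIEGI	C3
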