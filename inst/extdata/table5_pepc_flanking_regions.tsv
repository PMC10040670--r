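class	family	species	region	ptype
Musci	Funariaceae	Physcomitrella patens	AKGDPRIA(A/E/Q)L	C3
dicots	Amborellaceae	Amborella trichopoda	AKGDPGIAAL	C3
dicots	Apiaceae	Daucus carota	AKGDPGIA(A/E)L	C3
dicots	Asteraceae	Helianthus annuus	AKGDPGIAAL	C3
dicots	Brassicaceae	Arabidopsis thaliana	AKGDPGIAAL	C3
dicots	Brassicaceae	Arabidopsis halleri	AKGDPGIA(A/T)L	C3
dicots	Brassicaceae	Brassica napus	AKGDPGIAAL	C3
dicots	Brassicaceae	Brassica rapa	AKGDPGIAAL	C3
dicots	Bromeliaceae	Ananas comosus	AKGDPGIAAL	C3
dicots	Bromeliaceae	Neoregelia ampullacea	XXGDPGIAAL	C3
dicots	Chenopodiaceae	Beta vulgaris	AKGDPGIAAL	C3
dicots	Cucurbitaceae	Cucumis sativus	AKGDPGIAAL	C3
dicots	Euphorbiaceae	Manihot esculenta	AKGDPGIAAL	C3
dicots	Hydrocharitaceae	Flaveria trinervia	AKG(D/N)PGIAAL	C4
dicots	Hydrocharitaceae	Flaveria pringlei	AKGDPGIAAL	C3
dicots	Hydrocharitaceae	Hydrilla verticillata	AKGDP(G/V)IAAM	Facultative C4
dicots	Leguminosae	Vigna angularis	AKGNPGIA(A/V)L	C3
dicots	Leguminosae	Medicago truncatula	AKGDPGIAAL	C3
dicots	Leguminosae	lupinus angustifolius	AKGDPGIA(T/A)L	C3
dicots	Leguminosae	Glycine max	AKGDPKIA(A/G)L	C3
dicots	Leguminosae	Trifolium pratense	AKGDPGIAAL	C3
dicots	Leguminosae	Vigna radiata	AKG(N/D)P(G/E)IAAL	C3
dicots	Leguminosae	Phaseolus vulgaris	AKGDP(K/G)I(G/A)AL	C3
dicots	Malvaceae	Gossypium raimondii	AKGDPGIAAL	C3
dicots	Malvaceae	Corchorus capsularis	AKGDPGIAAL	C3
dicots	Musaceae	Musa acuminata	AKGDPGIAAI	C3
dicots	Palmae	Elaeis guineensis	AKGNPGIAAL	C3
dicots	Rosaceae	Prunus persica	AKGNPGIAAL	C3
dicots	Salicaceae	Populus trichocarpa	AKGDPGIAAL	C3
dicots	Sapindaceae	x Mokara cv. 'Yellow'	SKGNSGIAAL	C3
dicots	Solanaceae	Nicotiana attenuata	AKG(N/D)P(G/S)IAAL	C3
dicots	Solanaceae	Solanum tuberosum	AKGDPGIAAL	C3
dicots	Solanaceae	Solanum lycopersicum	AKGDPGIAAL	C3
dicots	Sterculiaceae	Theobroma cacao	AKGDPGIAAL	C3
monocots	Cyperaceae	Cyperus esculentus	AKGDPGIAAL	C3
monocots	Orchidaceae	Dendrobium officinale	TKGSSGIAAL	C3
monocots	Orchidaceae	Epidendrum stamfordianum	TKGSPGIAAL	C3
monocots	Orchidaceae	Leptotes bicolor	(A/T)KG(D/S)PGIA(T/A)L	C3
monocots	Orchidaceae	Microcoelia aphylla	(A/T)(K/R)G(N/D)PGIAAL	C3
monocots	Orchidaceae	Microcoelia exilis	A(K/Q)GDPGIAAL	C3
monocots	Orchidaceae	Phalaenopsis amabilis	AKGDPGIAAL	C3
monocots	Orchidaceae	Phalaenopsis equestris	AKGDPGIAAL	C3
monocots	Orchidaceae	Tillandsia usneoides	AKGDPGIAAL	C3
monocots	Orchidaceae	Vanilla planifolia	AKGNPGIASL	C3
monocots	Poaceae	Aegilops tauschii	AKGDPGIAAL	C3
monocots	Poaceae	Brachypodium distachyon	AKGDPGIAAL	C3
monocots	Poaceae	Echinochloa crus-galli	AKGDPGIVGF	C4
monocots	Poaceae	Echinochloa glabrescens	AKGDPGIAAL	C4
monocots	Poaceae	Zea luxurians	AKGDPGIAGL	C4
monocots	Poaceae	Hordeum vulgare	AKGNPGIAAL	C3
monocots	Poaceae	Hordeum vulgare subsp. vulgare	AKGNPGIAAL	C3
monocots	Poaceae	Hordeum vulgare subsp. spontaneum	AKGNPGIAAL	C3
monocots	Poaceae	Oryza sativa subsp. indica	AKGDPGIAAL	C3
monocots	Poaceae	Cenchrus americanus	AKADPIIAGL	C4
monocots	Poaceae	Saccharum officinarum	AKGDPGIAGL	C4
monocots	Poaceae	Saccharum spontaneum	AKGDPGIA(G/A)L	C4
monocots	Poaceae	Setaria italica	AKG(N/D)P(T/G)IA(S/E/G)L	C4
monocots	Poaceae	Sorghum bicolor	AKG(D/N)PGIA(A/G)(V/L)	C4
monocots	Poaceae	Triticum aestivum	AKGDPGIAAL	C3
monocots	Poaceae	Triticum dicoccoides	AKGDPRIAAL	C3
monocots	Poaceae	Triticum urartu	AKG(D/N)PGIAAL	C3
monocots	Poaceae	Triticum monococcum	AKGNPGIAAL	C3
monocots	Poaceae	Zea may	AKG(N/D)PGIA(G/A)(L/V)	C4
monocots	Poaceae	Zea mays subsp. mexicana	AKGDPGIAGL	C4
monocots	Poaceae	Zea mays subsp. parviglumis	AKGDPGIAGL	C4
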