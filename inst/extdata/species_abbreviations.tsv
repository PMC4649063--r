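abbreviation	name
A. bisporus	Agaricus bisporus
A. muscaria	Amanita muscaria
A. muscara	Amanita muscaria
A. thiersii	Amanita thiersii
A. subglabra	Auricularia subglabra
C. cinerea	Coprinopsis cinerea
F. mediterranea	Fomitiporia mediterranea
F. pinicola	Fomitopsis pinicola
G. trabeum	Gloeophyllum trabeum
G. luxurians	Gymnopus luxurians
G. marginata	Galerina marginata
H. cylindrosporum	Hebeloma cylindrosporum
H. annosum	Heterobasidion annosum
H. sublateritium	Hypholoma sublateritium
H. sublateriutium	Hypholoma sublateritium
J. argillacea	Jaapia argillacea
L. bicolor	Laccaria bicolor
P. involutus	Paxillus involutus
P. rubicondulus	Paxillus rubicondulus
P. croceum	Piloderma croceum
P. microcarpus	Pisolithus microcarpus
P. tinctorius	Pisolithus tinctorius
P. ostreatus	Pleurotus ostreatus
P. crispa	Plicaturopsis crispa
P. strigosozonata	Punctularia strigosozonata
P. strigozonata	Punctularia strigosozonata
P. chrysosporium	Phanerochaete chrysosporium
P. chrisosporium	Phanerochaete chrysosporium
S. citrinum	Scleroderma citrinum
S. commune	Schizophyllum commune
S. lacrymans	Serpula lacrymans
S. luteus	Suillus luteus
T. versicolor	Trametes versicolor
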