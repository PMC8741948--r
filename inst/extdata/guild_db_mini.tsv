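taxon	taxonomicLevel	trophicMode	guild	confidenceRanking	growthForm
Curvularia	genus	Pathotroph	Plant Pathogen	Highly Probable	Microfungus
Bipolaris	genus	Pathotroph	Plant Pathogen	Highly Probable	Microfungus
Cochliobolus	genus	Pathotroph	Plant Pathogen	Highly Probable	Microfungus
Exserohilum	genus	Pathotroph	Plant Pathogen	Probable	Microfungus
Helminthosporium	genus	Pathotroph	Fungal Parasite-Plant Pathogen	Probable	Microfungus
Magnaporthe	genus	Pathotroph	Plant Pathogen	Highly Probable	Microfungus
Ustilago	genus	Pathotroph	Plant Pathogen	Highly Probable	Smut
Puccinia	genus	Pathotroph	Plant Pathogen	Highly Probable	Rust
Penicillium	genus	Saprotroph	Dung Saprotroph-Undefined Saprotroph-Wood Saprotroph	Highly Probable	Microfungus
Talaromyces	genus	Saprotroph	Undefined Saprotroph	Probable	Microfungus
Paecilomyces	genus	Saprotroph	Clavicipitaceous Endophyte-Saprotroph	Probable	Microfungus
Chaetomium	genus	Saprotroph	Undefined Saprotroph	Probable	Microfungus
Humicola	genus	Saprotroph	Undefined Saprotroph	Probable	Microfungus
Thielavia	genus	Saprotroph	Undefined Saprotroph	Probable	Microfungus
Mortierella	genus	Saprotroph	Soil Saprotroph	Highly Probable	Microfungus
Coprinellus	genus	Saprotroph	Dung Saprotroph-Wood Saprotroph	Highly Probable	Agaricoid
Nigrospora	genus	Saprotroph	Undefined Saprotroph	Probable	Microfungus
Glomus	genus	Symbiotroph	Arbuscular Mycorrhizal	Highly Probable	Glomeromycete
Rhizophagus	genus	Symbiotroph	Arbuscular Mycorrhizal	Highly Probable	Glomeromycete
Funneliformis	genus	Symbiotroph	Arbuscular Mycorrhizal	Highly Probable	Glomeromycete
Sebacina	genus	Symbiotroph	Ectomycorrhizal-Orchid Mycorrhizal	Probable	Corticioid
Serendipita	genus	Symbiotroph	Orchid Mycorrhizal-Root Endophyte	Probable	Corticioid
Tuber	genus	Symbiotroph	Ectomycorrhizal	Highly Probable	Hypogeous
Phoma	genus	Pathotroph-Saprotroph	Plant Pathogen-Undefined Saprotroph	Probable	Microfungus
Macrophomina	genus	Pathotroph-Saprotroph	Plant Pathogen-Wood Saprotroph	Probable	Microfungus
Stemphylium	genus	Pathotroph-Saprotroph	Plant Pathogen-Undefined Saprotroph	Probable	Microfungus
Setophoma	genus	Pathotroph-Saprotroph	Plant Pathogen-Undefined Saprotroph	Probable	Microfungus
Colletotrichum	genus	Pathotroph-Symbiotroph	Plant Pathogen-Root Endophyte	Probable	Microfungus
Olpidium	genus	Pathotroph-Symbiotroph	Plant Pathogen-Root Endophyte	Probable	Chytrid
Moesziomyces	genus	Pathotroph-Symbiotroph	Plant Pathogen-Epiphyte	Probable	Yeast
Trichoderma	genus	Saprotroph-Symbiotroph	Fungal Parasite-Undefined Saprotroph-Root Endophyte	Probable	Microfungus
Clonostachys	genus	Saprotroph-Symbiotroph	Fungal Parasite-Undefined Saprotroph	Probable	Microfungus
Phialocephala	genus	Saprotroph-Symbiotroph	Dark Septate Endophyte-Undefined Saprotroph	Probable	Microfungus
Cladophialophora	genus	Saprotroph-Symbiotroph	Dark Septate Endophyte-Undefined Saprotroph	Probable	Microfungus
Fusarium	genus	Pathotroph-Saprotroph-Symbiotroph	Plant Pathogen-Endophyte-Wood Saprotroph	Highly Probable	Microfungus
Aspergillus	genus	Pathotroph-Saprotroph-Symbiotroph	Animal Pathogen-Endophyte-Undefined Saprotroph	Probable	Microfungus
Alternaria	genus	Pathotroph-Saprotroph-Symbiotroph	Plant Pathogen-Endophyte-Undefined Saprotroph	Probable	Microfungus
Cladosporium	genus	Pathotroph-Saprotroph-Symbiotroph	Plant Pathogen-Endophyte-Undefined Saprotroph	Probable	Microfungus
Rhizoctonia	genus	Pathotroph-Saprotroph-Symbiotroph	Plant Pathogen-Undefined Saprotroph-Ectomycorrhizal	Probable	Microfungus
Phomopsis	genus	Pathotroph-Saprotroph-Symbiotroph	Plant Pathogen-Endophyte-Undefined Saprotroph	Probable	Microfungus
Acremonium	genus	Saprotroph	Undefined Saprotroph	Possible	Microfungus
Mucor	genus	Saprotroph	Undefined Saprotroph	Possible	Microfungus
Epicoccum	genus	Pathotroph-Saprotroph	Plant Pathogen-Undefined Saprotroph	Possible	Microfungus
Curvibasidium	genus	Saprotroph	Undefined Saprotroph	Possible	Yeast
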