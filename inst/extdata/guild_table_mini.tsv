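taxon	rank	trophic_mode	guild	confidence
Fusarium	genus	Pathotroph	Plant Pathogen	Highly Probable
Verticillium	genus	Pathotroph	Plant Pathogen	Highly Probable
Alternaria	genus	Pathotroph-Saprotroph	Plant Pathogen-Wood Saprotroph	Probable
Botrytis	genus	Pathotroph	Plant Pathogen	Highly Probable
Rhizoctonia	genus	Pathotroph-Saprotroph	Plant Pathogen-Soil Saprotroph	Probable
Colletotrichum	genus	Pathotroph	Plant Pathogen	Highly Probable
Phoma	genus	Pathotroph-Saprotroph	Plant Pathogen	Probable
Bipolaris	genus	Pathotroph	Plant Pathogen	Probable
Magnaporthe	genus	Pathotroph	Plant Pathogen	Highly Probable
Candida	genus	Pathotroph	Animal Pathogen	Probable
Cryptococcus	genus	Pathotroph-Saprotroph	Animal Pathogen-Soil Saprotroph	Probable
Aspergillus	genus	Pathotroph-Saprotroph	Animal Pathogen-Plant Pathogen-Soil Saprotroph	Probable
Trichophyton	genus	Pathotroph	Animal Pathogen	Highly Probable
Penicillium	genus	Saprotroph	Soil Saprotroph	Probable
Trichoderma	genus	Saprotroph-Symbiotroph	Soil Saprotroph-Fungal Parasite	Probable
Mortierella	genus	Saprotroph	Soil Saprotroph	Highly Probable
Chaetomium	genus	Saprotroph	Dung Saprotroph-Soil Saprotroph	Probable
Cladosporium	genus	Saprotroph	Plant Saprotroph	Probable
Rhizophlyctis	genus	Saprotroph	Soil Saprotroph	Probable
Glomus	genus	Symbiotroph	Arbuscular Mycorrhizal	Highly Probable
Rhizophagus	genus	Symbiotroph	Arbuscular Mycorrhizal	Highly Probable
Suillus	genus	Symbiotroph	Ectomycorrhizal	Highly Probable
Nectriaceae	family	Pathotroph	Plant Pathogen	Probable
Ophiocordycipitaceae	family	Pathotroph	Animal Pathogen	Probable
Cordycipitaceae	family	Pathotroph	Animal Pathogen	Probable
Clavicipitaceae	family	Pathotroph	Animal Pathogen-Plant Pathogen	Probable
Pleosporaceae	family	Pathotroph-Saprotroph	Plant Pathogen-Soil Saprotroph	Possible
Ceratobasidiaceae	family	Pathotroph-Symbiotroph	Plant Pathogen-Orchid Mycorrhizal	Possible
Cystofilobasidiaceae	family	Saprotroph	Soil Saprotroph	Probable
Chaetomiaceae	family	Saprotroph	Dung Saprotroph-Soil Saprotroph	Probable
Microascaceae	family	Saprotroph	Soil Saprotroph	Probable
Lasiosphaeriaceae	family	Saprotroph	Dung Saprotroph-Undefined Saprotroph	Probable
Trichocomaceae	family	Saprotroph	Soil Saprotroph	Probable
Mortierellaceae	family	Saprotroph	Soil Saprotroph	Highly Probable
Rhizophlyctidaceae	family	Saprotroph	Soil Saprotroph	Probable
Hypocreaceae	family	Saprotroph-Symbiotroph	Soil Saprotroph-Fungal Parasite	Probable
Aspergillaceae	family	Pathotroph-Saprotroph	Animal Pathogen-Soil Saprotroph	Possible
Sporormiaceae	family	Saprotroph	Dung Saprotroph	Probable
Davidiellaceae	family	Saprotroph	Plant Saprotroph	Possible
Tremellaceae	family	Pathotroph-Saprotroph	Fungal Parasite-Undefined Saprotroph	Possible
Filobasidiaceae	family	Saprotroph	Undefined Saprotroph	Possible
Piskurozymaceae	family	Saprotroph	Soil Saprotroph	Possible
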