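term_id	name	parent_ids	ontology_key
HP:0000001	All		phenotype
HP:0000118	Phenotypic abnormality	HP:0000001	phenotype
HP:0002664	Neoplasm	HP:0000118	phenotype
HP:0001909	Leukemia	HP:0002664	phenotype
HP:0003002	Breast carcinoma	HP:0002664	phenotype
HP:0100526	Neoplasm of the lung	HP:0002664	phenotype
HP:0002860	Squamous cell carcinoma	HP:0002664	phenotype
HP:0100615	Ovarian neoplasm	HP:0002664	phenotype
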