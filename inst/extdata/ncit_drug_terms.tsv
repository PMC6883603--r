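term_id	name	parent_ids	ontology_key
NCIT:C1909	Pharmacologic Substance		drug
NCIT:C901001	Gefitinib	NCIT:C1909	drug
NCIT:C901002	Erlotinib	NCIT:C1909	drug
NCIT:C901003	Imatinib	NCIT:C1909	drug
NCIT:C901004	Trastuzumab	NCIT:C1909	drug
NCIT:C901005	Vemurafenib	NCIT:C1909	drug
NCIT:C901006	Dabrafenib	NCIT:C1909	drug
NCIT:C901007	Trametinib	NCIT:C1909	drug
NCIT:C901008	Cetuximab	NCIT:C1909	drug
NCIT:C901009	Bevacizumab	NCIT:C1909	drug
NCIT:C901010	Pembrolizumab	NCIT:C1909	drug
NCIT:C901011	Nivolumab	NCIT:C1909	drug
NCIT:C901012	Crizotinib	NCIT:C1909	drug
NCIT:C901013	Osimertinib	NCIT:C1909	drug
NCIT:C901014	Cisplatin	NCIT:C1909	drug
NCIT:C901015	Docetaxel	NCIT:C1909	drug
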