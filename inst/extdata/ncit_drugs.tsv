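drug_name	ncit_id
Gefitinib	NCIT:C901001
Erlotinib	NCIT:C901002
Imatinib	NCIT:C901003
Trastuzumab	NCIT:C901004
Vemurafenib	NCIT:C901005
Dabrafenib	NCIT:C901006
Trametinib	NCIT:C901007
Cetuximab	NCIT:C901008
Bevacizumab	NCIT:C901009
Pembrolizumab	NCIT:C901010
Nivolumab	NCIT:C901011
Crizotinib	NCIT:C901012
Osimertinib	NCIT:C901013
Cisplatin	NCIT:C901014
Docetaxel	NCIT:C901015
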