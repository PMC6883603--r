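alias	generic
Iressa	Gefitinib
Tarceva	Erlotinib
Gleevec	Imatinib
Glivec	Imatinib
Herceptin	Trastuzumab
Zelboraf	Vemurafenib
Tafinlar	Dabrafenib
Mekinist	Trametinib
Erbitux	Cetuximab
Avastin	Bevacizumab
Keytruda	Pembrolizumab
Opdivo	Nivolumab
Xalkori	Crizotinib
Tagrisso	Osimertinib
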