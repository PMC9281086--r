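antigen_name	sequence	hla_allele	source_note
MAGE-A3	KVAELVHFL	HLA-A*02:01	CAPED database TAA nonamer
MAGE-A10	GLYDGMEHL	HLA-A*02:01	CAPED database TAA nonamer
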