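gene_symbol	hpo_id
GRIN2B	HP:0001250
SCN2A	HP:0001250
SCN2A	HP:0002123
CACNA1A	HP:0001251
GRIN1	HP:0000007
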