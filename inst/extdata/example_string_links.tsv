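protein1 protein2 combined_score
GRIN2B GRIN1 950
GRIN2B DLG4 900
GRIN1 DLG4 870
NBEA GRIN2B 410
NBEA DLG4 380
SCN2A GRIN2B 620
SCN2A GRIN1 580
CACNA1A SCN2A 530
CACNA1A NBEA 210
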