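# Published counts of detected prescribed herbal materials per preparation
# and barcode, with the total number of PHMs of each prescription.
preparation	n_phms	detected_its2	detected_trnl	detected_union
BYW	8	8	5	8
DHW	36	25	18	28
NJW	9	9	4	9
YGW	9	6	4	7
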