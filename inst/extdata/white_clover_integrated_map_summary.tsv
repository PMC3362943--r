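group	n_loci	length_cm
LG1a	106	159.1
LG1b	113	190.9
LG2a	107	122.9
LG2b	98	207.8
LG3a	124	172.5
LG3b	146	142.6
LG4a	141	157.0
LG4b	134	177.1
LG5a	118	164.5
LG5b	108	156.2
LG6a	44	109.05
LG6b	63	132.4
LG7a	86	155.7
LG7b	101	151.5
LG8a	146	166.1
LG8b	108	146.0
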