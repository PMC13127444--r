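area	dataset	n_sites	n_samples
AMOR	amor_new	5	250
AMOR	amor_published	16	417
WNAG	wnag	3	95
MAR	mar	2	43
NWPO	nwpo	14	91
SPO	spo	11	84
SCS	scs	10	134
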