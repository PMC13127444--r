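area	O2	NO3	NH4	Mn
AMOR	628	629	629	644
WNAG	95	0	0	0
MAR	41	43	0	0
NWPO	67	91	91	0
SPO	37	71	61	73
SCS	96	134	134	134
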