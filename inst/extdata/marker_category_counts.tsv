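population	HH	AH	HA
Pop1	10862	2976	2753
Pop2	8996	1913	2189
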