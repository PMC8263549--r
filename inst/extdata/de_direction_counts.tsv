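direction	n_genes
up_in_lowland	4205
up_in_upland	3448
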