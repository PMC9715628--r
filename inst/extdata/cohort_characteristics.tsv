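cohort	phenotype	n_yes	n_total	printed_percent
PIAMA	allergy	67	348	19.3
PIAMA	ige_sensitized	162	348	46.6
EVA-PR	allergy	267	481	55.5
EVA-PR	ige_sensitized	311	481	64.7
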