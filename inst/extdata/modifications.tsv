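name	target	delta_mass	fixed
carbamidomethyl	C	57.02146	TRUE
pyridylethyl	C	105.05785	TRUE
oxidation_m	M	15.99491	FALSE
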