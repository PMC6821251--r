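Pre-eclampsia	ORPHA:275555
pre-eclamptic toxemia	ORPHA:275555
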