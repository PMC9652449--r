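name	protospacer_start	strand	pam
demo_site	5	+	NGG
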