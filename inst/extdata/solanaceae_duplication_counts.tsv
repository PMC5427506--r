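species	mechanism	n
tomato	total	70
tomato	tandem	42
tomato	ectopic	27
tomato	segmental	0
tomato	unanchored	1
potato	total	194
potato	tandem	118
potato	ectopic	76
potato	segmental	0
potato	unanchored	0
pepper	total	40
pepper	tandem	19
pepper	ectopic	16
pepper	segmental	1
pepper	unanchored	4
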