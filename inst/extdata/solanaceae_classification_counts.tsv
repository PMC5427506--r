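species	subclass	category	n
tomato	TNL	intact	17
tomato	TNL	TN	7
tomato	TNL	NL	3
tomato	TNL	N	4
tomato	CNL	intact	90
tomato	CNL	TN	6
tomato	CNL	NL	50
tomato	CNL	N	76
tomato	RNL	intact	2
tomato	RNL	TN	0
tomato	RNL	NL	0
tomato	RNL	N	0
potato	TNL	intact	31
potato	TNL	TN	18
potato	TNL	NL	4
potato	TNL	N	17
potato	CNL	intact	93
potato	CNL	TN	72
potato	CNL	NL	129
potato	CNL	N	80
potato	RNL	intact	2
potato	RNL	TN	0
potato	RNL	NL	0
potato	RNL	N	1
pepper	TNL	intact	5
pepper	TNL	TN	0
pepper	TNL	NL	4
pepper	TNL	N	7
pepper	CNL	intact	65
pepper	CNL	TN	29
pepper	CNL	NL	92
pepper	CNL	N	102
pepper	RNL	intact	1
pepper	RNL	TN	0
pepper	RNL	NL	1
pepper	RNL	N	0
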