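subclass	n
CNL	150
TNL	22
RNL	4
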