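branch	gains	losses
pepper	40	86
potato+tomato	112	31
tomato	24	118
potato	103	50
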