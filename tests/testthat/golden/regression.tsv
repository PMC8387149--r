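slope	intercept	r_squared	n_points	r2_ci_low	r2_ci_high
1.0444043993683	1.30774329698201	0.844269793923878	5	0.41795623518075	1
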