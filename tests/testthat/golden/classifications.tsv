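trace_id	genotype	mean_burst_duration_ms	label
WTL_01	WTL	166.460790801864	normal
WTL_02	WTL	153.647517497266	normal
WTL_03	WTL	177.992051760752	normal
WTL_04	WTL	169.631472783164	normal
WTL_05	WTL	147.541811553242	short
WTL_06	WTL	160.565660310091	normal
WTL_07	WTL	179.181551367032	normal
WTL_08	WTL	175.174849146382	normal
WTL_09	WTL	161.79019113627	normal
WTL_10	WTL	161.070746437954	normal
WTL_11	WTL	173.874199827948	normal
WTL_12	WTL	184.632929323978	elongated
ELG_01	ELG	458.580805514233	elongated
ELG_02	ELG	526.798087599849	elongated
ELG_03	ELG	540.283119719527	elongated
ELG_04	ELG	472.710973676985	elongated
ELG_05	ELG	555.692100235469	elongated
ELG_06	ELG	514.524616881691	elongated
ELG_07	ELG	447.665232026012	elongated
ELG_08	ELG	499.573235013017	elongated
ELG_09	ELG	547.078320311744	elongated
ELG_10	ELG	497.485197376224	elongated
ELG_11	ELG	552.112973910096	elongated
ELG_12	ELG	536.331647558417	elongated
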