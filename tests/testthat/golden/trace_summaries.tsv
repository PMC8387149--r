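trace_id	genotype	group_role	n_bursts	mean_burst_duration_s	sd_burst_duration_s	burst_frequency_hz	firing_rate_hz	mean_spikes_per_burst	mean_ap_frequency_per_burst_hz
WTL_01	WTL	wildtype_reference	76	0.166460790801864	0.106727997686837	0.422222222222222	5.57777777777778	13.2105263157895	82.9872805282132
WTL_02	WTL	wildtype_reference	94	0.153647517497266	0.0923906034433174	0.522222222222222	6.51666666666667	12.436170212766	83.8761178471881
WTL_03	WTL	wildtype_reference	77	0.177992051760752	0.125062813021411	0.427777777777778	6.12222222222222	14.2727272727273	83.2157052621839
WTL_04	WTL	wildtype_reference	82	0.169631472783164	0.0843452400849986	0.455555555555556	6.18888888888889	13.5609756097561	82.2246081690737
WTL_05	WTL	wildtype_reference	84	0.147541811553242	0.0719869578096102	0.466666666666667	5.66111111111111	12.1190476190476	84.8333411247307
WTL_06	WTL	wildtype_reference	81	0.160565660310091	0.0930420146361004	0.45	5.83888888888889	12.9506172839506	83.9297396949228
WTL_07	WTL	wildtype_reference	95	0.179181551367032	0.0925867013260231	0.527777777777778	7.61666666666667	14.4315789473684	82.754817142539
WTL_08	WTL	wildtype_reference	91	0.175174849146382	0.0871392138430065	0.505555555555556	7.21666666666667	14.2747252747253	83.2456027667946
WTL_09	WTL	wildtype_reference	82	0.16179019113627	0.0862956318481733	0.455555555555556	5.87777777777778	12.9024390243902	83.8478189376181
WTL_10	WTL	wildtype_reference	81	0.161070746437954	0.0909607901964845	0.45	5.95555555555556	13.2098765432099	86.0170143161398
WTL_11	WTL	wildtype_reference	72	0.173874199827948	0.0891404912520769	0.4	5.67777777777778	14.1666666666667	83.7720045327845
WTL_12	WTL	wildtype_reference	84	0.184632929323978	0.112336986187414	0.466666666666667	7.16666666666667	15.3452380952381	85.0610153233579
ELG_01	ELG	mutant	70	0.458580805514233	0.234200095510044	0.388888888888889	13.5611111111111	34.8428571428571	76.244233965735
ELG_02	ELG	mutant	76	0.526798087599849	0.254320337138367	0.422222222222222	16.7944444444444	39.7763157894737	76.0328610130701
ELG_03	ELG	mutant	74	0.540283119719527	0.303647419371375	0.411111111111111	16.8444444444444	40.9594594594595	76.5970691921386
ELG_04	ELG	mutant	80	0.472710973676985	0.255341203605354	0.444444444444444	16.3666666666667	36.8	78.9857941942445
ELG_05	ELG	mutant	68	0.555692100235469	0.272952897135843	0.377777777777778	16.0611111111111	42.5147058823529	76.7928268237317
ELG_06	ELG	mutant	61	0.514524616881691	0.375967699798711	0.338888888888889	13.2833333333333	39.1639344262295	76.7853888961345
ELG_07	ELG	mutant	75	0.447665232026012	0.277145925753486	0.416666666666667	14.3777777777778	34.44	77.9674304569016
ELG_08	ELG	mutant	76	0.499573235013017	0.258829127266816	0.422222222222222	16.3555555555556	38.7105263157895	77.8615956022058
ELG_09	ELG	mutant	80	0.547078320311744	0.247836936148317	0.444444444444444	18.4833333333333	41.5875	76.0535749957274
ELG_10	ELG	mutant	67	0.497485197376224	0.249108864069227	0.372222222222222	14.1111111111111	37.8955223880597	76.1502090860241
ELG_11	ELG	mutant	72	0.552112973910096	0.25480206081359	0.4	16.7722222222222	41.9166666666667	76.6208077392588
ELG_12	ELG	mutant	73	0.536331647558417	0.30493244750872	0.405555555555556	16.6055555555556	40.9315068493151	77.1471341389649
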