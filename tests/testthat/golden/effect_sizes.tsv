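comparison_id	assay	group_a	group_b	n_a	n_b	mean_difference	ci_low	ci_high	cohens_d	n_boot	seed	ci_method	percent_change
bsA_vortex	vortex	ctl	bsA	20	20	11.4909650917111	9.92771230365713	13.6043748767748	3.89230490046152	5000	809535779	bca	642.870873465441
bsB_vortex	vortex	ctl	bsB	20	20	70.6355789513196	63.4301708056992	79.2022016010676	5.46498866934295	5000	404862479	bca	3951.76175158061
bsC_vortex	vortex	ctl	bsC	20	20	167.908462636777	151.801762099478	183.957830479582	6.29464695094179	5000	189179	bca	9393.76798867905
bsA_eshock	eshock	ctl	bsA	20	20	64.8468203768945	51.1501640134427	80.0013553548633	2.72329244673822	5000	326231506	bca	72.5875656095455
bsB_eshock	eshock	ctl	bsB	20	20	123.091384185214	101.370801431606	146.708668806476	3.28388513756867	5000	2069041853	bca	137.784765291246
bsC_eshock	eshock	ctl	bsC	20	20	264.680002567027	233.276162031512	298.749228286651	4.86910359775282	5000	1664368553	bca	296.274774001322
hsA_heat	heat	hsA_c	hsA	20	20	66.8007912013072	58.1353294366866	75.7244881821184	4.61452859110308	5000	66833205	bca	1740.579093551
hsB_heat	heat	hsB_c	hsB	20	20	429.980975584307	381.672430251852	532.774512215996	3.82128344534341	5000	236376819	bca	10083.398019283
hsA_eshock	eshock	hsA_c	hsA	20	20	119.474949054594	99.9170169350834	141.839849071651	3.44943888879804	5000	1876932991	bca	125.26308079941
hsB_eshock	eshock	hsB_c	hsB	20	20	73.3182291409803	57.050442062556	93.0887667777741	2.47719274997778	5000	1599588873	bca	73.1808222565118
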