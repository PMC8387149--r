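genotype	time_s	fraction_seizing
hsA	10	0.1
hsA	20	0.3
hsA	30	0.55
hsA	40	0.7
hsA	50	0.75
hsA	60	0.8
hsA	70	0.85
hsA	80	0.85
hsA	90	0.85
hsA	100	0.85
hsA	110	0.9
hsA	120	0.95
hsB	10	0
hsB	20	0.1
hsB	30	0.4
hsB	40	0.5
hsB	50	0.6
hsB	60	0.8
hsB	70	0.85
hsB	80	0.9
hsB	90	0.9
hsB	100	0.9
hsB	110	0.95
hsB	120	1
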