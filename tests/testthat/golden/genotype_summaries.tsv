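genotype	n	burst_duration_ms	burst_duration_sd_ms	burst_frequency_hz	firing_rate_ap_per_s	ap_count_per_burst	ap_frequency_per_burst_hz
WTL	12	167.630314328829	94.3346201112877	0.4625	6.28472222222222	13.5733824054696	83.8137554704622
ELG	12	512.403025818605	274.090417843321	0.403703703703704	15.8013888888889	39.1282495766836	76.9365771753448
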