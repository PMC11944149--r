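strain	mu	mu_sd	qs	qs_sd	yield_bg	b	c
WT	0.670	0.002	8.46	0.42	0.444	0.30410	-1.44
ALE-1	0.886	0.030	11.57	0.52	0.425	0.42324	-1.55
ALE-2	0.869	0.015	10.79	0.40	0.447	0.39574	-1.57
ALE-3	0.891	0.024	11.97	0.72	0.414	0.41514	-1.20
ALE-4	0.819	0.013	10.29	0.27	0.442	0.36869	-1.42
ALE-5	0.934	0.011	11.82	0.57	0.439	0.40408	-1.11
ALE-6	0.936	0.021	12.46	0.37	0.417	0.34908	0.35
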