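contrast	n_induced	n_repressed	n_bound	n_bound_induced	n_bound_repressed	pct_of_induced	pct_of_bound_up	pct_of_repressed	pct_of_bound_down
SC_38_vs_C	517	909	1093	2	104	0.39	0.18	11.44	9.52
SC_43_vs_C	18	362	1785	1	36	5.56	0.06	9.94	2.02
HEP_43_vs_C	155	133	676	11	3	7.10	1.63	2.26	0.44
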