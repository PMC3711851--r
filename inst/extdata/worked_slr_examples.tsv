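gene	contrast	mean_c	mean_hs	slr_published
Canx	SC_38_vs_C	8.69	7.54	-1.15
Canx	HEP_43_vs_C	10.29	10.07	-0.22
Dnaja1	SC_38_vs_C	9.50	8.41	-1.09
Dnaja1	HEP_43_vs_C	11.65	12.72	1.07
Hsp90b1	SC_38_vs_C	10.93	9.90	-1.03
Hsp90b1	HEP_43_vs_C	11.78	11.63	-0.15
Fkbp7	SC_38_vs_C	7.16	8.75	1.59
Fkbp7	HEP_43_vs_C	5.51	5.61	0.10
Psmd10	SC_38_vs_C	6.92	8.25	1.33
Psmd10	HEP_43_vs_C	6.83	6.77	-0.06
Hspa1a	HEP_43_vs_C	6.93	13.10	6.17
Dnajb1	SC_38_vs_C	11.40	10.78	-0.62
Dnajb1	HEP_43_vs_C	8.48	12.88	4.40
Dnaja4	SC_38_vs_C	8.23	8.79	0.56
Dnaja4	HEP_43_vs_C	6.18	9.98	3.80
Hspa1b	SC_38_vs_C	4.96	5.03	0.07
Hspa1b	HEP_43_vs_C	9.55	13.22	3.67
Hsph1	SC_38_vs_C	7.77	7.64	-0.13
Hsph1	HEP_43_vs_C	9.18	11.65	2.47
Dnajb4	SC_38_vs_C	10.05	10.21	0.16
Dnajb4	HEP_43_vs_C	8.83	10.19	1.36
Serpinh1	SC_38_vs_C	5.78	6.21	0.43
Serpinh1	HEP_43_vs_C	6.36	7.72	1.36
Hsp90ab1	SC_38_vs_C	9.94	9.35	-0.59
Hsp90ab1	HEP_43_vs_C	11.29	12.31	1.02
Hspe1	SC_38_vs_C	7.03	7.09	0.06
Hspe1	HEP_43_vs_C	8.63	9.64	1.01
Spen	SC_38_vs_C	7.18	8.30	1.12
Spen	SC_43_vs_C	7.18	7.06	-0.12
Spen	HEP_43_vs_C	6.35	6.04	-0.31
Asb14	SC_38_vs_C	5.02	6.12	1.10
Asb14	SC_43_vs_C	5.02	5.05	0.03
1700109H08Rik	SC_38_vs_C	9.46	10.41	0.95
1700109H08Rik	SC_43_vs_C	9.46	9.42	-0.04
1700109H08Rik	HEP_43_vs_C	4.71	4.85	0.14
6330503K22Rik	SC_38_vs_C	10.09	7.93	-2.16
Topbp1	SC_38_vs_C	8.01	6.44	-1.57
Topbp1	SC_43_vs_C	8.01	7.47	-0.54
Fam178a	SC_38_vs_C	7.88	6.36	-1.52
Mov10l1	SC_38_vs_C	8.54	7.47	-1.07
Zfand2a	HEP_43_vs_C	6.43	8.44	2.01
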