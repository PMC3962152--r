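gene	rank_pct_a	p_a	fc_a	rank_pct_b	p_b	fc_b	printed_class
APC	7	1.99e-06	-4.782	21	3.15e-08	-1.272	under
APP	2	4.68e-09	-19.629	1	9.83e-64	-3.799	under
AXIN1	27	5.00e-03	-1.766	41	3.70e-02	-1.607	under
CCND1	27	6.00e-03	-2.555	39	1.90e-02	-1.08	under
CDC42	3	8.32e-08	-2.631	15	2.44e-12	-1.249	under
CDH1	18	3.16e-04	-2.573	6	1.31e-28	-2.816	under
CREBBP	1	1.95e-09	-3.821	12	1.66e-16	-1.408	under
CTNNA1	22	1.00e-03	-3.401	1	4.41e-60	-3.627	under
EP300	14	5.14e-05	-1.732	34	2.00e-03	-1.147	under
KAT2B	2	2.52e-08	-3.205	7	4.59e-25	-2.279	under
NFKB1	10	3.40e-07	-29.14	5	1.09e-19	-1.8	under
NOTCH2	11	1.93e-05	-5.629	18	4.85e-10	-1.189	under
PSEN1	2	8.94e-09	-2.626	14	5.38e-14	-1.338	under
RAC1	42	1.28e-01	-1.223	10	3.25e-18	-1.438	under
SMAD3	2	6.69e-09	-10.45	27	3.03e-05	-1.191	under
VEGFA	33	2.60e-02	-6.262	1	1.25e-52	-3.364	under
AKT1	16	9.24e-05	2.159	26	3.30e-06	1.224	over
CDH2	30	6.00e-03	3.89	4	5.73e-32	2.648	over
EGFR	34	1.40e-02	3.384	39	5.00e-03	1.083	over
GSK3B	31	7.00e-03	1.398	13	1.63e-14	1.364	over
HDAC1	5	2.38e-07	2.406	6	1.26e-24	1.542	over
JUN	26	2.00e-03	3.799	20	1.12e-09	1.957	over
LEF1	5	3.97e-07	13.361	1	8.79e-50	3.083	over
NOTCH1	15	6.77e-05	2.394	1	5.05e-45	2.461	over
NOTCH3	20	4.16e-04	11.153	2	2.37e-38	3.021	over
SMAD2	8	2.25e-06	1.791	9	1.41e-20	1.358	over
SMAD4	2	2.50e-02	1.276	37	4.57e-42	2.024	over
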