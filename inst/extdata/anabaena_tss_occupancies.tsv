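sequence	state	label	P	dF_kBT	S	P_NS
alr0705	TSS	-64	0.219	1.42	0.77	0.054
alr0705	site	28	0.288	1.66	0.85	0.054
argC	TSS	-19	0.220	2.10	0.70	0.027
argC	site	50	0.329	2.50	0.59	0.027
nifB	TSS	-221	0.315	3.47	0.39	0.010
nifB	site	-270	0.444	3.81	0.86	0.010
conR	TSS	-101	0.151	1.97	0.58	0.021
conR	site	-30	0.349	2.80	0.91	0.021
furA	TSS	-27	0.449	3.45	1.35	0.014
furA	site	-87	0.390	3.32	1.16	0.014
furB	TSS1	-83	0.302	2.39	0.86	0.028
furB	TSS2	-60	0.276	2.30	0.79	0.028
furB	site	-10	0.149	1.68	0.28	0.028
petH	TSS1	-188	0.199	3.01	0.74	0.010
petH	TSS2	-63	0.117	2.48	0.33	0.010
petH	site	-220	0.166	2.83	0.40	0.010
petF	TSS1	-93	0.198	3.03	0.58	0.010
petF	TSS2	-31	0.268	3.33	0.67	0.010
petF	site	1	0.101	2.35	0.33	0.010
ntcA	TSS1	-180	0.098	0.96	0.029	0.038
ntcA	TSS2	-136	0.205	1.69	0.73	0.038
ntcA	TSS3	-39	0.292	2.05	0.85	0.038
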