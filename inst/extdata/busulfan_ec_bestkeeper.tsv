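gene	geo_mean_cp	ar_mean_cp	min_cp	max_cp	sd_cp	cv_pct	pearson_r	p_value
ywhaz	24.33	24.51	22.17	32.58	2.37	9.66	0.996	0.001
actb	20.97	21.11	19.06	26.98	1.95	9.23	0.978	0.001
alas1	27.71	27.9	25.42	36.32	2.55	9.16	0.996	0.001
b2m	22.82	22.97	20.81	30.07	2.02	8.8	0.982	0.001
tfrc	27.15	27.32	25.2	35.58	2.29	8.4	0.99	0.001
ppia	23.15	23.27	20.73	28.96	1.92	8.26	0.962	0.001
hprt1	28.1	28.27	25.89	36.58	2.33	8.24	0.99	0.001
gapdh	21.13	21.23	19.62	26.18	1.7	8	0.958	0.001
rplp0	21.41	21.5	19.86	26.52	1.54	7.14	0.992	0.001
gusb	26.79	26.89	25.23	32.66	1.89	7.01	0.984	0.001
hmbs	28.83	28.94	26.98	35.4	2.03	7	0.994	0.001
ubc	23.13	23.24	21.04	29.42	1.59	6.85	0.835	0.002
tbp	28.15	28.2	26.93	32.47	1.22	4.32	0.96	0.001
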