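gene	mean_ct	sd	variance	ddct	ddct_sd	mean_fold	fold_sd	true_fold
actb	21.105	2.672	7.139	-2.05	2.67	1.54	0.038	0.622
gapdh	21.348	2.085	4.97	-1.70	2.08	1.31	0.073	0.387
rplp0	21.499	2.534	4.773	-1.65	2.53	1.45	0.055	0.540
ppia	23.373	2.534	6.423	-1.82	2.53	1.64	0.049	0.711
ubc	23.24	2.584	6.68	-2.21	2.58	1.31	0.036	0.379
ywhaz	24.512	3.462	11.986	-2.35	3.46	2.17	0.018	1.115
hprt1	28.266	3.519	12.383	-2.38	3.52	2.20	0.017	1.138
hmbs	28.939	2.842	8.077	-1.96	2.84	1.84	0.036	0.878
b2m	22.97	3.02	9.123	-2.16	3.02	1.82	0.028	0.86
tfrc	27.322	3.484	12.136	-2.13	3.48	1.33	0.020	0.408
alas1	27.896	3.656	13.365	-2.48	3.66	2.26	0.014	1.175
gusb	26.894	2.587	6.693	-1.66	2.59	1.90	0.053	0.923
tbp	28.198	1.831	3.352	-1.27	1.83	1.47	0.012	0.558
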