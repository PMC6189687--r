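gene	bestkeeper_r	bestkeeper_rank	genorm_m	genorm_rank	normfinder_stability	normfinder_rank	ddct_mean_fold	ddct_rank	geo_mean	final_rank
ywhaz	0.996	1	0.228	1	0.386	9	2.166	3	2.28	1
alas1	0.996	1	0.284	3	0.456	11	2.26	1	2.40	2
hmbs	0.994	3	0.561	6	0.126	1	1.838	5	3.08	3
hprt1	0.99	5	0.228	1	0.444	10	2.20	2	3.16	4
gusb	0.984	7	0.683	8	0.15	2	1.896	4	4.60	5
b2m	0.982	8	0.482	5	0.316	5	1.815	6	5.89	6
actb	0.978	9	0.650	7	0.187	3	1.540	8	6.24	7
tfrc	0.99	5	0.372	4	0.333	7	1.327	11	6.26	8
rplp0	0.992	4	0.799	11	0.378	8	1.454	10	7.70	9
ppia	0.962	10	0.719	9	0.329	6	1.637	7	7.84	10
gapdh	0.958	12	0.766	10	0.301	4	1.308	12	8.71	11
tbp	0.96	11	0.883	12	0.494	12	1.472	9	10.93	12
ubc	0.835	13	0.963	13	0.599	13	1.30	13	13.00	13
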