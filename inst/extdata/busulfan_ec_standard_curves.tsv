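gene	r_squared	slope_A	efficiency_E	consistent
actb	1	-3.482	0.937	TRUE
gapdh	0.99	-3.402	0.968	TRUE
eef1a1	0.997	-3.282	1.017	TRUE
rplp0	0.999	-0.325	0.999	FALSE
ppia	0.999	-0.452	0.948	FALSE
ubc	0.999	-0.365	0.982	FALSE
ywhaz	1	-3.37	0.906	FALSE
hprt1	1	-3.625	0.887	TRUE
hmbs	0.996	-3.272	1.021	TRUE
b2m	0.998	-3.405	1.021	FALSE
tfrc	1.0	-3.215	0.966	FALSE
alas1	0.989	-3.502	1.047	FALSE
gusb	0.992	-3.042	0.93	FALSE
tbp	1	-3.37	1.131	FALSE
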