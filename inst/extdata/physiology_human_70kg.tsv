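tissue	V_T	f_EW	f_IW	f_NL	f_NP	AP	RA_alb	RA_lip	pH
adipose	0.1857	0.141	0.039	0.7900	0.0020	0.40	0.049	0.068	7.0
bone	0.0856	0.100	0.346	0.0174	0.0016	0.67	0.100	0.050	7.0
brain	0.0200	0.162	0.620	0.0391	0.0015	0.40	0.048	0.041	7.0
gut	0.0171	0.282	0.475	0.0487	0.0163	2.41	0.158	0.141	7.0
heart	0.0047	0.320	0.456	0.0115	0.0166	2.25	0.157	0.160	7.0
kidney	0.0044	0.273	0.483	0.0207	0.0162	5.03	0.130	0.137	7.0
liver	0.0257	0.161	0.573	0.0348	0.0252	4.56	0.086	0.161	7.0
lung	0.0076	0.336	0.446	0.0219	0.0140	3.91	0.212	0.168	7.0
muscle	0.4000	0.118	0.630	0.0100	0.0072	1.53	0.064	0.059	7.0
skin	0.0371	0.382	0.291	0.0284	0.0111	1.32	0.277	0.096	7.0
spleen	0.0026	0.207	0.579	0.0201	0.0198	3.18	0.097	0.207	7.0
rest	0.1000	0.280	0.450	0.0300	0.0100	2.00	0.120	0.120	7.0
plasma	0.0424	0.945	0.000	0.0023	0.0013	0.00	1.000	1.000	7.4
red_blood_cells	0.0347	0.000	0.603	0.0017	0.0029	0.50	0.000	0.000	7.22
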