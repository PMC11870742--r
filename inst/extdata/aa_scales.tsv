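residue	kyte_doolittle	parker	emini_surface	cf_helix	cf_sheet	cf_turn	cf_turn_f1	cf_turn_f2	cf_turn_f3	cf_turn_f4
A	1.8	2.1	0.49	1.42	0.83	0.66	0.060	0.076	0.035	0.058
R	-4.5	4.2	0.95	0.98	0.93	0.95	0.070	0.106	0.099	0.085
N	-3.5	7.0	0.81	0.67	0.89	1.56	0.161	0.083	0.191	0.091
D	-3.5	10.0	0.78	1.01	0.54	1.46	0.147	0.110	0.179	0.081
C	2.5	1.4	0.26	0.70	1.19	1.19	0.149	0.053	0.117	0.128
Q	-3.5	6.0	0.84	1.11	1.10	0.98	0.074	0.098	0.037	0.098
E	-3.5	7.8	0.84	1.51	0.37	0.74	0.056	0.060	0.077	0.064
G	-0.4	5.7	0.48	0.57	0.75	1.56	0.102	0.085	0.190	0.152
H	-3.2	2.1	0.66	1.00	0.87	0.95	0.140	0.047	0.093	0.054
I	4.5	-8.0	0.34	1.08	1.60	0.47	0.043	0.034	0.013	0.056
L	3.8	-9.2	0.40	1.21	1.30	0.59	0.061	0.025	0.036	0.070
K	-3.9	5.7	0.97	1.16	0.74	1.01	0.055	0.115	0.072	0.095
M	1.9	-4.2	0.48	1.45	1.05	0.60	0.068	0.082	0.014	0.055
F	2.8	-9.2	0.42	1.13	1.38	0.60	0.059	0.041	0.065	0.065
P	-1.6	2.1	0.75	0.57	0.55	1.52	0.102	0.301	0.034	0.068
S	-0.8	6.5	0.65	0.77	0.75	1.43	0.120	0.139	0.125	0.106
T	-0.7	5.2	0.70	0.83	1.19	0.96	0.086	0.108	0.065	0.079
W	-0.9	-10.0	0.51	1.08	1.37	0.96	0.077	0.013	0.064	0.167
Y	-1.3	-1.9	0.76	0.69	1.47	1.14	0.082	0.065	0.114	0.125
V	4.2	-3.7	0.36	1.06	1.70	0.50	0.062	0.048	0.028	0.053
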