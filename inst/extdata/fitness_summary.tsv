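clone	host	mean	sd	n
A1	PP	0.298	0.062	6
B1	PP	0.180	0.226	6
C1	PP	-0.630	0.219	6
C2	PP	0.121	0.168	6
D1	PP	-0.875	0.083	6
D2	PP	-0.697	0.236	6
D3	PP	0.272	0.167	6
D4	PP	0.327	0.069	6
E1	PP	-0.935	0.140	6
E2	PP	-0.855	0.123	6
E3	PP	-0.651	0.199	6
E4	PP	-0.640	0.170	6
E5	PP	-0.583	0.185	6
E6	PP	0.287	0.065	6
E7	PP	-0.490	0.122	6
E8	PP	0.362	0.228	6
F1	PP	-0.480	0.209	6
F2	PP	-0.219	0.264	6
F3	PP	-0.694	0.167	6
F4	PP	0.142	0.041	6
F5	PP	-0.550	0.278	6
F6	PP	-0.401	0.078	6
F7	PP	0.387	0.108	6
F8	PP	0.101	0.157	6
F9	PP	-0.058	0.114	6
F10	PP	-0.066	0.050	6
F11	PP	0.283	0.181	6
F12	PP	0.287	0.101	6
F13	PP	-0.048	0.168	6
F14	PP	-0.845	0.199	6
F15	PP	0.494	0.178	6
F16	PP	0.445	0.117	6
B1	ERA	-1.373	0.262	6
C1	ERA	-0.437	0.221	6
D1	ERA	-0.277	0.159	6
D2	ERA	-0.527	0.316	6
E1	ERA	-0.432	0.097	6
E2	ERA	-0.256	0.104	6
E3	ERA	-0.395	0.222	6
E4	ERA	0.075	0.275	6
E6	ERA	-0.379	0.237	6
F2	ERA	0.005	0.265	6
F3	ERA	-0.264	0.140	6
F4	ERA	-0.242	0.163	6
F5	ERA	-0.045	0.182	6
F7	ERA	0.510	0.242	6
F8	ERA	0.698	0.122	6
F11	ERA	-0.332	0.258	6
F12	ERA	-0.222	0.185	6
F15	ERA	1.028	0.148	6
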