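analyte	season	soil_type	mean	sd	n
moisture_pct	dry	rhizosphere	14.85	3.12	12
moisture_pct	dry	bulk	7.65	2.41	12
moisture_pct	rainy	rhizosphere	12.67	2.82	12
moisture_pct	rainy	bulk	11.04	2.77	12
pH	dry	rhizosphere	7.72	0.31	12
pH	dry	bulk	7.95	0.34	12
pH	rainy	rhizosphere	7.87	0.19	12
pH	rainy	bulk	8.03	0.19	12
Ca_mg_kg	dry	rhizosphere	1037.11	78.90	12
Ca_mg_kg	dry	bulk	1004.68	34.21	12
Ca_mg_kg	rainy	rhizosphere	1987.62	148.62	12
Ca_mg_kg	rainy	bulk	1917.81	120.85	12
NH4_mg_kg	dry	rhizosphere	3.04	0.83	12
NH4_mg_kg	dry	bulk	2.06	0.89	12
NH4_mg_kg	rainy	rhizosphere	13.55	1.81	12
NH4_mg_kg	rainy	bulk	14.10	2.95	12
TN_mg_kg	dry	rhizosphere	1.70	0.49	12
TN_mg_kg	dry	bulk	1.07	0.43	12
TN_mg_kg	rainy	rhizosphere	1.76	1.02	12
TN_mg_kg	rainy	bulk	4.49	2.67	12
C_N_ratio	dry	rhizosphere	17.74	7.72	12
C_N_ratio	dry	bulk	30.76	2.61	12
C_N_ratio	rainy	rhizosphere	25.80	6.50	12
C_N_ratio	rainy	bulk	7.92	2.30	12
NO3_mg_kg	dry	rhizosphere	25.95	6.49	12
NO3_mg_kg	dry	bulk	18.21	10.76	12
NO3_mg_kg	rainy	rhizosphere	49.48	13.73	12
NO3_mg_kg	rainy	bulk	28.81	7.20	12
EC_uS_cm	dry	rhizosphere	322.31	88.15	12
EC_uS_cm	dry	bulk	224.34	75.50	12
EC_uS_cm	rainy	rhizosphere	232.97	47.57	12
EC_uS_cm	rainy	bulk	179.02	20.07	12
OM_pct	dry	rhizosphere	3.61	1.69	12
OM_pct	dry	bulk	1.98	0.62	12
OM_pct	rainy	rhizosphere	3.98	1.11	12
OM_pct	rainy	bulk	2.94	0.73	12
K_mg_kg	dry	rhizosphere	186.22	56.60	12
K_mg_kg	dry	bulk	125.15	42.49	12
K_mg_kg	rainy	rhizosphere	305.90	81.11	12
K_mg_kg	rainy	bulk	228.87	49.43	12
Mg_mg_kg	dry	rhizosphere	102.34	34.14	12
Mg_mg_kg	dry	bulk	70.09	12.05	12
Mg_mg_kg	rainy	rhizosphere	164.83	32.35	12
Mg_mg_kg	rainy	bulk	134.34	26.09	12
P_mg_kg	dry	rhizosphere	0.17	0.09	12
P_mg_kg	dry	bulk	0.11	0.05	12
P_mg_kg	rainy	rhizosphere	0.80	0.12	12
P_mg_kg	rainy	bulk	0.61	0.09	12
Na_mg_kg	dry	rhizosphere	6.79	2.34	12
Na_mg_kg	dry	bulk	6.56	1.48	12
Na_mg_kg	rainy	rhizosphere	8.44	2.61	12
Na_mg_kg	rainy	bulk	7.13	1.34	12
TC_mg_kg	dry	rhizosphere	27.48	7.43	12
TC_mg_kg	dry	bulk	29.48	6.21	12
TC_mg_kg	rainy	rhizosphere	26.35	11.85	12
TC_mg_kg	rainy	bulk	21.54	9.85	12
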