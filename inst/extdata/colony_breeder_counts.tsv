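line	generation	n_phenotyped	n_breeders	n_male	n_female
HCR	0	NA	26	13	13
HCR	1	116	28	14	14
HCR	2	137	28	14	14
HCR	3	160	28	14	14
HCR	4	131	26	13	13
HCR	5	151	28	14	14
HCR	6	151	30	15	15
HCR	7	133	30	15	15
HCR	8	185	28	13	15
HCR	9	234	30	14	16
HCR	10	238	29	13	16
HCR	11	202	34	16	18
HCR	12	195	30	14	16
HCR	13	240	34	16	18
HCR	14	222	30	15	15
HCR	15	232	32	16	16
HCR	16	210	38	19	19
HCR	17	283	42	21	21
HCR	18	270	46	23	23
HCR	19	227	42	20	22
HCR	20	248	44	22	22
HCR	21	235	50	25	25
HCR	22	258	48	24	24
HCR	23	227	48	24	24
HCR	24	215	44	22	22
HCR	25	264	50	25	25
HCR	26	297	44	22	22
HCR	27	290	NA	NA	NA
HCR	28	225	NA	NA	NA
LCR	0	NA	26	13	13
LCR	1	125	26	13	13
LCR	2	126	26	13	13
LCR	3	167	30	15	15
LCR	4	138	26	13	13
LCR	5	150	26	13	13
LCR	6	155	26	13	13
LCR	7	141	26	13	13
LCR	8	143	28	14	14
LCR	9	198	27	14	13
LCR	10	150	27	13	14
LCR	11	245	28	14	14
LCR	12	202	26	13	13
LCR	13	216	28	14	14
LCR	14	209	28	14	14
LCR	15	231	30	15	15
LCR	16	141	30	15	15
LCR	17	254	38	19	19
LCR	18	246	38	19	19
LCR	19	238	45	22	23
LCR	20	233	50	25	25
LCR	21	226	39	19	20
LCR	22	204	50	25	25
LCR	23	191	52	26	26
LCR	24	172	50	25	25
LCR	25	225	44	22	22
LCR	26	240	50	25	25
LCR	27	254	NA	NA	NA
LCR	28	226	NA	NA	NA
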