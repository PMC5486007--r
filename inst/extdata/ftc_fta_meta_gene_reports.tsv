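study_id	gene_id	symbol	direction
study04	2896	GRN	up
study05	440	ASNS	up
study05	762	CA4	down
study05	771	CA12	up
study05	1306	COL15A1	down
study05	1649	DDIT3	up
study05	1959	EGR2	down
study05	2358	FPR2	up
study05	2697	GJA1	down
study05	3400	ID4	down
study05	3486	IGFBP3	up
study05	3590	IL11RA	down
study05	3708	ITPR1	down
study05	3725	JUN	down
study05	3912	LAMB1	down
study05	4982	TNFRSF11B	down
study05	6414	SEPP1	down
study05	7033	TFF3	down
study05	8857	FCGBP	down
study05	9413	FAM189A2	down
study05	11072	DUSP14	down
study05	22795	NID2	down
study05	23089	PEG10	up
study05	23180	RFTN1	down
study05	55830	GLT8D1	down
study05	129080	EMID1	down
study05	221395	GPR116	down
study06	1733	DIO1	down
study06	5172	SLC26A4	down
study06	7033	TFF3	down
study06	7881	KCNAB1	down
study07	1649	DDIT3	up
study07	22795	NID2	down
study07	129080	EMID1	down
study08	2896	GRN	up
study08	3400	ID4	down
study08	3491	CYR61	down
study09	440	ASNS	up
study09	762	CA4	down
study09	953	ENTPD1	down
study09	1363	CPE	down
study09	3309	HSPA5	down
study09	5583	PRKCH	down
study09	7881	KCNAB1	down
study09	8490	RGS5	down
study09	9413	FAM189A2	down
study09	9452	ITM2A	down
study09	9518	GDF15	up
study09	10404	CPQ	down
study09	23180	RFTN1	down
study09	83483	PLVAP	down
study09	221395	GPR116	down
study10	3486	IGFBP3	up
study10	7033	TFF3	down
study10	7038	TG	down
study10	7173	TPO	down
study11	2358	FPR2	up
study11	2697	GJA1	down
study11	3590	IL11RA	down
study11	3708	ITPR1	down
study11	3912	LAMB1	down
study11	4982	TNFRSF11B	down
study11	10404	CPQ	down
study11	23089	PEG10	up
study11	55830	GLT8D1	down
study12	771	CA12	up
study12	1733	DIO1	down
study12	3043	HBB	down
study12	3164	NR4A1	down
study12	9413	FAM189A2	down
study12	22925	PLA2R1	down
study13	185	AGTR1	down
study13	1306	COL15A1	down
study13	8490	RGS5	down
study13	83483	PLVAP	down
study14	822	CAPG	down
study14	953	ENTPD1	down
study14	1959	EGR2	down
study14	5172	SLC26A4	down
study14	5583	PRKCH	down
study14	6414	SEPP1	down
study14	10404	CPQ	down
study15	3043	HBB	down
study16	185	AGTR1	down
study16	744	MPPED2	down
study16	762	CA4	down
study16	1164	CKS2	up
study16	1959	EGR2	down
study16	2354	FOSB	down
study16	3164	NR4A1	down
study16	3491	CYR61	down
study16	3725	JUN	down
study16	5172	SLC26A4	down
study16	7881	KCNAB1	down
study16	9452	ITM2A	down
study16	11072	DUSP14	down
study16	22925	PLA2R1	down
study17	744	MPPED2	down
study17	822	CAPG	down
study17	1164	CKS2	up
study17	1363	CPE	down
study17	2354	FOSB	down
study17	3309	HSPA5	down
study17	7038	TG	down
study17	7173	TPO	down
study17	8857	FCGBP	down
study17	9518	GDF15	up
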