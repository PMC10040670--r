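family	species	gene	gene_id	protein_id	location	aa_length	molecular_weight	subcellular	pI	high_expression_tissue
beta-CA	Sorghum	SbCA3	SORBI_3003G234200	KXG32970	Chr3:57297987-57310502	448	48986.93	cytoplasm	8.74	leaf shoot
beta-CA	Maize	ZmCA3	Zm00001d044099	Zm00001d044099_P002	Chr3:219075378-219080211	452	49363.10	cytoplasm	8.74	leaf
beta-CA	Millet	SiCA3	SETIT_003882mg	KQL06049	Chr5:30333130-30336956	336	26378.56	cytoplasm	8.80	leaf shoot spike
beta-CA	Rice	OsCA3	Os01g0639900	Os01t0639900-01	Chr1:25696671-25705077	272	29117.42	chloroplast	8.41	leaf spike shoot
beta-CA	Wheat	TaCA3-3A	TraesCS3A02G230000	TraesCS3A02G230000.2	Chr3A:430330494-430337814	259	28076.34	chloroplast	8.35	leaf shoot spike
beta-CA	Wheat	TaCA3-3B	TraesCS3B02G259300	TraesCS3B02G259300.1	Chr3B:417258446-417265886	258	27963.18	chloroplast	8.35	leaf shoot spike
beta-CA	Wheat	TaCA3-3D	TraesCS3D02G223300	TraesCS3D02G223300.1	Chr3D:304327703-304335024	258	27977.21	chloroplast	8.35	leaf shoot spike
RbcS	Sorghum	SbRbcS1	SORBI_3005G042000	EES09292	Chr5:3876057-3877378	169	19058.87	Chloroplast	8.77	leaf
RbcS	Maize	ZmRbcS2	Zm00001d052595	Zm00001d052595_T001	Chr4:194257728-194258862	170	19150.99	Chloroplast	9.10	leaf
RbcS	Millet	SiRbcS5	SETIT_023465mg	KQL15806	Chr3:24102022-24103068	169	19082.08	Chloroplast	8.64	leaf
RbcS	Rice	OsRbcS1	Os12g0274700	Os12t0274700-01	Chr12:10080505-10081588	175	19646.68	Chloroplast	9.04	leaf
RbcS	Wheat	TaRbcS8-5A	TraesCS5A02G165700	TraesCS5A02G165700.1	Chr5AL:354314588-354315579	175	19490.51	Chloroplast	8.80	leaf
RbcS	Wheat	TaRbcS8-5B	TraesCS5B02G162800	TraesCS5B02G162800.1	Chr5BL:300097036-300098231	175	19490.51	Chloroplast	8.80	leaf
RbcS	Wheat	TaRbcS8-5D	TraesCS5D02G169900	TraesCS5D02G169900.2	Chr5DL:266325112-266326079	175	19490.51	Chloroplast	8.80	leaf
PEPC	Sorghum	SbPEPC4	SORBI_3010G160700	EER89889	Chr10:47244445-47253575	1028	115731.7	Chloroplast	6.12	leaf
PEPC	Maize	ZmPEPC4	Zm00001d046170	Zm00001d046170_P001	Chr9:68851094-68856482	970	109341	Chloroplast	5.73	leaf
PEPC	Millet	SiPEPC4	SETIT_005789mg	KQL10919	Chr4:28034710-28043142	964	109982.7	Chloroplast	5.95	leaf
PEPC	Wheat	TaPEPC4-7A	TraesCS7A02G345400	TraesCS7A02G345400.1	Chr7AL:507757190-507763146	919	104542.4	Chloroplast	5.90	leaf
PEPC	Wheat	TaPEPC4-7B	TraesCS7B02G237900	TraesCS7B02G237900.1	Chr7BL:443292417-443299286	892	101122.3	Chloroplast	5.65	leaf
PEPC	Wheat	TaPEPC4-7D	TraesCS7D02G333900	TraesCS7D02G333900.1	Chr7DL:425502517-425509832	968	109614.9	Chloroplast	5.66	leaf
ME	Sorghum	SbME4	SORBI_3003G036200	EES00150	Chr3:3317184-3322427	636	69377.63	chloroplast	5.49	leaf
ME	Maize	ZmME4	GRMZM2G085019	GRMZM2G085019_P01	Chr3:7276387-7281737	636	69818.85	Chloroplast	6.20	leaf
ME	Millet	SiME4	SETIT_000645mg	KQL04777	Chr5:11687298-11692722	639	70037.89	chloroplast	6.31	leaf
ME	Rice	OsME4	Os01g0188400	Os01t0188400-01	Chr1:4739271-4744472	639	69865.84	chloroplast	6.70	spike, root
ME	Wheat	TaME4-3A	TraesCS3A02G108900	TraesCS3A02G108900.1	Chr3AL:74781464-74787353	648	70942.07	chloroplast	6.64	spike, leaf
ME	Wheat	TaME4-3B	TraesCS3B02G128000	TraesCS3B02G128000.1	Chr3BS:106962508-106968100	591	65203.5	chloroplast	5.86	spike, leaf
ME	Wheat	TaME4-3D	TraesCS3D02G110700	TraesCS3D02G110700.1	Chr3DL:64370009-64375502	642	70286.32	chloroplast	6.64	spike, leaf
MDH	Sorghum	SbMDH3	SORBI_3007G166200	KXG25371	Chr7:60144110-60147894	434	46880.56	chloroplast	5.51	leaf
MDH	Maize	ZmMDH3	Zm00001d031899	Zm00001d031899_P002	Chr1:205992187-205996030	432	46786.63	chloroplast	6.49	leaf
MDH	Millet	SiMDH3	SETIT_013632mg	KQL03004	Chr6:35757135-35760887	493	52791.61	chloroplast	6.24	leaf
MDH	Rice	OsMDH3	Os08g0562100	Os08t0562100-01	Chr8:28141176-28144882	433	47008.9	chloroplast	6.96	leaf
MDH	Wheat	TaMDH3-7B	TraesCS7B02G197000	TraesCS7B02G197000.2	Chr7BL:339613762-339617788	431	46682.5	chloroplast	6.62	leaf
MDH	Wheat	TaMDH3-7D	TraesCS7B02G197000	TraesCS7D02G283900.1	Chr7DS:296507630-296511690	431	46814.67	chloroplast	6.96	leaf
MDH	Wheat	TaMDH3-U	TraesCSU02G135100	TraesCSU02G135100.2	ChrUn:116430718-116434600	431	46814.67	chloroplast	7.52	leaf
PPDK	Sorghum	SbPPDK1.1	SORBI_3009G132900	KXG21962	Chr9:48726358-48738528	948	102490.21	chloroplast	5.54	leaf
PPDK	Maize	ZmPPDK1.1	Zm00001d038163	Zm00001d038163_P002	Chr6:150024486-150035717	936	101251	chloroplast	5.76	leaf
PPDK	Millet	SiPPDK1.1	LOC101760933	XP_004962130.1	Chr3:21258962-21273297	945	102424.94	chloroplast	5.38	leaf
PPDK	Rice	OsPPDK1.1	Os05g0405000	Os05t0405000-01	Chr5:19718538-19737605	947	102787.88	chloroplast	5.98	leaf
PPDK	Wheat	TaPPDK1-1A.1	TraesCS1A02G253400	TraesCS1A02G253400.1	Chr1AL:445257710-445277310	939	101861.56	chloroplast	5.64	leaf
PPDK	Wheat	TaPPDK1-1B.1	TraesCS1B02G264900	TraesCS1B02G264900.1	Chr1BL:465683651-465701383	939	101950.77	chloroplast	5.68	leaf
PPDK	Wheat	TaPPDK1-1D.1	TraesCS1D02G252900	TraesCS1D02G252900.1	Chr1DL:345264118-345282757	939	101845.56	chloroplast	5.64	leaf
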