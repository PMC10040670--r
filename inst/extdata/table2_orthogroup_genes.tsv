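family	orthogroup	c4_type	foxtail_millet	sorghum	maize	rice	wheat_A	wheat_B	wheat_D
beta-CA	beta-CA1	no	KQL24850	KXG35798	Zm00001d020764;Zm00001d005920	Os09t0464000	TraesCS5A02G245700	TraesCS5B02G243100	TraesCS5D02G252400
beta-CA	beta-CA2	no	KQL06053	KXG32978	-	Os01t0640000	TraesCS3A02G230100	TraesCS3B02G259400	TraesCS3D02G223200
beta-CA	beta-CA3	yes	KQL06049	KXG32970	Zm00001d044099	Os01t0639900	TraesCS3A02G230000	TraesCS3B02G259300	TraesCS3D02G223300
beta-CA	beta-CA4	no	KQL06051	KXG32975	Zm00001d044095	-	-	-	-
beta-CA	beta-CA5	no	-	-	-	-	TraesCS7A02G454300	TraesCS7B02G354800	TraesCS7D02G443400
beta-CA	beta-CA6	no	-	-	-	-	TraesCS7A02G454500	TraesCS7B02G354900	TraesCS7D02G443500
beta-CA	beta-CA7	no	-	-	-	-	TraesCS7A02G454400	-	-
beta-CA	beta-CA8	no	-	KXG32973	-	-	-	-	-
beta-CA	beta-CA9	no	-	-	Zm00001d044096	-	-	-	-
beta-CA	beta-CA10	no	-	-	Zm00001d011454	-	-	-	-
PEPC	PEPC1	no	SETIT_028826mg	SORBI_3002G167000	Zm00001d020057	Os09t0315700	TraesCS5A02G181800	TraesCS5B02G179800	TraesCS5D02G186200
PEPC	PEPC2	no	SETIT_000184mg	SORBI_3003G301800	Zm00001d012702	Os01t0758300	TraesCS3A02G306700	TraesCS3B02G329800	TraesCS3D02G295200
PEPC	PEPC3	no	SETIT_016228mg	SORBI_3004G106900	Zm00001d053453	Os02t0244700	TraesCS6A02G195600	TraesCS6B02G223100	TraesCS6D02G183200
PEPC	PEPC4	yes	SETIT_005789mg	SORBI_3010G160700	Zm00001d046170	-	TraesCS7A02G345400	TraesCS7B02G237900	TraesCS7D02G333900
PEPC	PEPC5	no	SETIT_000160mg	-	-	Os01t0208700	TraesCS3A02G134200	TraesCS3B02G168000	TraesCS3D02G150500
PEPC	PEPC6	no	-	SORBI_3007G106500	-	Os08t0366000	-	-	-
ME	ME1	no	SETIT_000808mg	SORBI_3003G292400	Zm00001d012764	Os01t0743500	TraesCS3A02G275600	TraesCS3B02G309300	TraesCS3D02G275500
ME	ME2	no	SETIT_000774mg	SORBI_3003G280900	Zm00001d043601	Os01t0723400	TraesCS3A02G285900	TraesCS3B02G320200	TraesCS3D02G285700
ME	ME3	no	SETIT_021600mg	SORBI_3009G069600	Zm00001d037693	Os05t0186300	TraesCS1A02G122500	TraesCS1B02G141700	TraesCS1D02G123400
ME	ME4	yes	SETIT_000645mg	SORBI_3003G036200	Zm00001eb121470	Os01t0188400	TraesCS3A02G108900	TraesCS3B02G128000	TraesCS3D02G110700
ME	ME5	no	-	SORBI_3003G036000	Zm00001d037961	-	-	-	-
ME	ME6	no	-	-	Zm00001d037962	-	-	-	-
ME	ME7	no	-	-	Zm00001d010358	-	-	-	-
MDH	MDH1	no	SETIT_036550mg	SORBI_3001G219300	Zm00001d032695	Os10t0478200	TraesCS1A02G155200	TraesCS1B02G172400	TraesCS1D02G153900
MDH	MDH2	no	SETIT_010442mg	SORBI_3006G170800	Zm00001d002741	Os04t0551200	-	-	-
MDH	MDH3	yes	SETIT_013632mg	SORBI_3007G166200	Zm00001d031899	Os08t0562100	TraesCSU02G135100	TraesCS7B02G197000	TraesCS7D02G283900
MDH	MDH4	no	SETIT_013547mg	SORBI_3007G137600	Zm00001d032187	Os08t0434300	TraesCS1A02G348500	TraesCS1B02G363100	TraesCS1D02G351500
MDH	MDH5	no	SETIT_030117mg	OQU90313	Zm00001d022229	Os07t0630800	-	-	-
MDH	MDH6	no	SETIT_022438mg	SORBI_3008G186200	Zm00001d041243	Os12t0632700	TraesCS5A02G014300	TraesCS5B02G012400	TraesCS5D02G019700
MDH	MDH7	no	SETIT_036365mg	SORBI_3001G073900	Zm00001d034241	Os03t0773800	TraesCS5A02G407700	TraesCS5B02G412500	TraesCS5D02G417600
MDH	MDH8	no	SETIT_022574mg	SORBI_3009G240700	Zm00001d039089	Os05t0574400	TraesCS1A02G412900	TraesCS1B02G443200	TraesCS1D02G420500
MDH	MDH9	no	SETIT_002110mg	SORBI_3003G238500	Zm00001d044042	Os01t0649100	TraesCS3A02G234800	TraesCS3B02G265000	TraesCS3D02G236200
MDH	MDH10	no	-	-	Zm00001d014030	-	-	-	-
MDH	MDH11	no	-	-	Zm00001d019330	-	-	-	-
MDH	MDH12	no	-	-	-	-	TraesCS5A02G549900	TraesCSU02G127700	-
MDH	MDH13	no	SETIT_029817mg	-	-	-	-	-	-
MDH	MDH14	no	-	SORBI_3007G166300	-	-	-	-	-
MDH	MDH15	no	-	-	-	-	TraesCS7A02G386600	TraesCS7B02G289400	TraesCS7D02G383100
MDH	MDH16	no	-	-	-	Os01t0829800	-	-	-
MDH	MDH17	no	SETIT_022252mg	-	-	-	-	-	-
MDH	MDH18	no	-	-	Zm00001d050409	-	-	-	-
MDH	MDH19	no	-	-	Zm00001d009640	-	-	-	-
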