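family	rice	foxtail_millet	sorghum	maize	wheat	cdd_id	pfam_ids
beta-CA	3	4	5	5	16	cl00391	PF00484
RbcS	4	5	1	2	24	cl01843	PF12338;PF00101
PEPC	5	5	5	4	15	cl21521	PF00311
NADP-ME	4	4	6	6	12	cl27704	PF03949;PF00390
MDH	10	11	10	13	26	cl27704	PF02866
PPDK	1	2	2	2	4	cl27021	PF02896;PF01326;PF00391
Total	27	31	29	32	97		
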