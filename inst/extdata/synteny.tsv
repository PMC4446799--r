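family	species	locus_id	flanks_up	flanks_down
EIF1A	mouse	A1	LOCUS_EIF1A_ROD_U2,LOCUS_EIF1A_ROD_U1	LOCUS_EIF1A_ROD_D1,LOCUS_EIF1A_ROD_D2
EIF1A	rat	A1	LOCUS_EIF1A_ROD_U2,LOCUS_EIF1A_ROD_U1	LOCUS_EIF1A_ROD_D1,LOCUS_EIF1A_ROD_D2
EIF1A	cattle	A2	LOCUS_EIF1A_BOV_U2,LOCUS_EIF1A_BOV_U1	LOCUS_EIF1A_BOV_D1,LOCUS_EIF1A_BOV_D2
EIF2S3	human	A1	LOCUS_EIF2S3_APE_U2,LOCUS_EIF2S3_APE_U1	LOCUS_EIF2S3_APE_D1,LOCUS_EIF2S3_APE_D2
EIF2S3	chimpanzee	A1	LOCUS_EIF2S3_APE_U2,LOCUS_EIF2S3_APE_U1	LOCUS_EIF2S3_APE_D1,LOCUS_EIF2S3_APE_D2
EIF2S3	gorilla	A1	LOCUS_EIF2S3_APE_U2,LOCUS_EIF2S3_APE_U1	LOCUS_EIF2S3_APE_D1,LOCUS_EIF2S3_APE_D2
EIF2S3	orangutan	A1	LOCUS_EIF2S3_APE_U2,LOCUS_EIF2S3_APE_U1	LOCUS_EIF2S3_APE_D1,LOCUS_EIF2S3_APE_D2
EIF2S3	rhesus	A2	LOCUS_EIF2S3_OWM_U2,LOCUS_EIF2S3_OWM_U1	LOCUS_EIF2S3_OWM_D1,LOCUS_EIF2S3_OWM_D2
EIF2S3	baboon	A2	LOCUS_EIF2S3_OWM_U2,LOCUS_EIF2S3_OWM_U1	LOCUS_EIF2S3_OWM_D1,LOCUS_EIF2S3_OWM_D2
EIF2S3	marmoset	A3	LOCUS_EIF2S3_NWM_U2,LOCUS_EIF2S3_NWM_U1	LOCUS_EIF2S3_NWM_D1,LOCUS_EIF2S3_NWM_D2
EIF2S3	squirrel_monkey	A3	LOCUS_EIF2S3_NWM_U2,LOCUS_EIF2S3_NWM_U1	LOCUS_EIF2S3_NWM_D1,LOCUS_EIF2S3_NWM_D2
EIF2S3	cattle	A4	LOCUS_EIF2S3_BOV_U2,LOCUS_EIF2S3_BOV_U1	LOCUS_EIF2S3_BOV_D1,LOCUS_EIF2S3_BOV_D2
RPS4	mouse	A1	LOCUS_RPS4_ROD_U2,LOCUS_RPS4_ROD_U1	LOCUS_RPS4_ROD_D1,LOCUS_RPS4_ROD_D2
RPS4	rat	A1	LOCUS_RPS4_ROD_U2,LOCUS_RPS4_ROD_U1	LOCUS_RPS4_ROD_D1,LOCUS_RPS4_ROD_D2
RPS4	opossum	A2	LOCUS_RPS4_MAR1_U2,LOCUS_RPS4_MAR1_U1	LOCUS_RPS4_MAR1_D1,LOCUS_RPS4_MAR1_D2
RPS4	wallaby	A2	LOCUS_RPS4_MAR1_U2,LOCUS_RPS4_MAR1_U1	LOCUS_RPS4_MAR1_D1,LOCUS_RPS4_MAR1_D2
RPS4	opossum	A3	LOCUS_RPS4_MAR2_U2,LOCUS_RPS4_MAR2_U1	LOCUS_RPS4_MAR2_D1,LOCUS_RPS4_MAR2_D2
RPS4	wallaby	A3	LOCUS_RPS4_MAR2_U2,LOCUS_RPS4_MAR2_U1	LOCUS_RPS4_MAR2_D1,LOCUS_RPS4_MAR2_D2
RPS4	cattle	A4	LOCUS_RPS4_BOV_U2,LOCUS_RPS4_BOV_U1	LOCUS_RPS4_BOV_D1,LOCUS_RPS4_BOV_D2
UBA1	marmoset	A1	LOCUS_UBA1_YCTX_U2,LOCUS_UBA1_YCTX_U1	LOCUS_UBA1_YCTX_D1,LOCUS_UBA1_YCTX_D2
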