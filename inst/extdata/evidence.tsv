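family	species	locus_id	orf_status	transcribed	p_parent	omega	origin	pattern
EIF1A	mouse	A1	intact	TRUE	0.083	0.0010	Y	broad
EIF1A	rat	A1	intact	TRUE	0.085	0.0010	Y	broad
EIF1A	cattle	A2	truncated	FALSE	0.050	NA	unresolved	silent
EIF2S3	human	A1	intact	TRUE	0.061	0.075	X	testis_specific
EIF2S3	chimpanzee	A1	intact	TRUE	0.060	0.075	X	testis_specific
EIF2S3	gorilla	A1	intact	TRUE	0.059	NA	X	testis_specific
EIF2S3	orangutan	A1	intact	TRUE	0.058	NA	X	testis_specific
EIF2S3	rhesus	A2	intact	TRUE	0.055	NA	X	testis_specific
EIF2S3	baboon	A2	unknown	TRUE	0.056	NA	X	testis_specific
EIF2S3	marmoset	A3	intact	TRUE	0.064	NA	X	broad
EIF2S3	squirrel_monkey	A3	intact	TRUE	0.066	0.075	X	broad
EIF2S3	cattle	A4	truncated	TRUE	0.012	NA	unresolved	broad
RPS4	mouse	A1	intact	TRUE	0.078	0.0059	unresolved	testis_specific
RPS4	rat	A1	intact	TRUE	0.079	0.0059	unresolved	testis_specific
RPS4	opossum	A2	intact	TRUE	0.148	0.0132	unresolved	broad
RPS4	wallaby	A2	intact	TRUE	0.149	0.0132	unresolved	broad
RPS4	opossum	A3	intact	TRUE	0.151	0.0053	unresolved	broad
RPS4	wallaby	A3	intact	TRUE	0.152	0.0053	unresolved	broad
RPS4	cattle	A4	intact	TRUE	0.139	0.0180	unresolved	testis_specific
UBA1	marmoset	A1	intact	TRUE	0.112	0.3381	Y	testis_specific
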