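family	species	chrom_class	locus_id	has_introns	mechanism_hint
EIF1A	human	X	X	TRUE	ancestral
EIF1A	chimpanzee	X	X	TRUE	ancestral
EIF1A	rhesus	X	X	TRUE	ancestral
EIF1A	marmoset	X	X	TRUE	ancestral
EIF1A	mouse	X	X	TRUE	ancestral
EIF1A	rat	X	X	TRUE	ancestral
EIF1A	cattle	X	X	TRUE	ancestral
EIF1A	human	Y	Y	TRUE	ancestral
EIF1A	chimpanzee	Y	Y	TRUE	ancestral
EIF1A	rhesus	Y	Y	TRUE	ancestral
EIF1A	marmoset	Y	Y	TRUE	ancestral
EIF1A	cattle	Y	Y	TRUE	ancestral
EIF1A	mouse	A	A1	FALSE	retro
EIF1A	rat	A	A1	FALSE	retro
EIF1A	cattle	A	A2	FALSE	retro
EIF2S3	human	X	X	TRUE	ancestral
EIF2S3	chimpanzee	X	X	TRUE	ancestral
EIF2S3	gorilla	X	X	TRUE	ancestral
EIF2S3	orangutan	X	X	TRUE	ancestral
EIF2S3	rhesus	X	X	TRUE	ancestral
EIF2S3	baboon	X	X	TRUE	ancestral
EIF2S3	marmoset	X	X	TRUE	ancestral
EIF2S3	squirrel_monkey	X	X	TRUE	ancestral
EIF2S3	mouse	X	X	TRUE	ancestral
EIF2S3	rat	X	X	TRUE	ancestral
EIF2S3	cattle	X	X	TRUE	ancestral
EIF2S3	mouse	Y	Y	TRUE	ancestral
EIF2S3	rat	Y	Y	TRUE	ancestral
EIF2S3	cattle	Y	Y	TRUE	ancestral
EIF2S3	human	A	A1	FALSE	retro
EIF2S3	chimpanzee	A	A1	FALSE	retro
EIF2S3	gorilla	A	A1	FALSE	retro
EIF2S3	orangutan	A	A1	FALSE	retro
EIF2S3	rhesus	A	A2	FALSE	retro
EIF2S3	baboon	A	A2	FALSE	retro
EIF2S3	marmoset	A	A3	FALSE	retro
EIF2S3	squirrel_monkey	A	A3	FALSE	retro
EIF2S3	cattle	A	A4	FALSE	retro
RPS4	human	X	X	TRUE	ancestral
RPS4	chimpanzee	X	X	TRUE	ancestral
RPS4	rhesus	X	X	TRUE	ancestral
RPS4	marmoset	X	X	TRUE	ancestral
RPS4	mouse	X	X	TRUE	ancestral
RPS4	rat	X	X	TRUE	ancestral
RPS4	cattle	X	X	TRUE	ancestral
RPS4	opossum	X	X	TRUE	ancestral
RPS4	wallaby	X	X	TRUE	ancestral
RPS4	human	Y	Y	TRUE	ancestral
RPS4	chimpanzee	Y	Y	TRUE	ancestral
RPS4	rhesus	Y	Y	TRUE	ancestral
RPS4	marmoset	Y	Y	TRUE	ancestral
RPS4	mouse	A	A1	FALSE	retro
RPS4	rat	A	A1	FALSE	retro
RPS4	opossum	A	A2	FALSE	retro
RPS4	wallaby	A	A2	FALSE	retro
RPS4	opossum	A	A3	FALSE	retro
RPS4	wallaby	A	A3	FALSE	retro
RPS4	cattle	A	A4	FALSE	retro
UBA1	human	X	X	TRUE	ancestral
UBA1	chimpanzee	X	X	TRUE	ancestral
UBA1	rhesus	X	X	TRUE	ancestral
UBA1	marmoset	X	X	TRUE	ancestral
UBA1	squirrel_monkey	X	X	TRUE	ancestral
UBA1	mouse	X	X	TRUE	ancestral
UBA1	rat	X	X	TRUE	ancestral
UBA1	cattle	X	X	TRUE	ancestral
UBA1	opossum	X	X	TRUE	ancestral
UBA1	squirrel_monkey	Y	Y	TRUE	ancestral
UBA1	mouse	Y	Y	TRUE	ancestral
UBA1	rat	Y	Y	TRUE	ancestral
UBA1	opossum	Y	Y	TRUE	ancestral
UBA1	marmoset	A	A1	TRUE	dna
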