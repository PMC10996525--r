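##fileformat=VCFv4.2
##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">
##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">
##INFO=<ID=TECOV,Number=1,Type=Float,Description="Fraction of SV covered by a TE">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Haploid genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S001	S002	S003
chr1	3000	sv01	N	<INS>	.	PASS	SVTYPE=INS;SVLEN=100;TECOV=0.9	GT	0	1	1
chr1	5000	sv02	N	<INS>	.	PASS	SVTYPE=INS;SVLEN=49;TECOV=0.9	GT	1	1	0
chr1	7000	sv03	N	<INS>	.	PASS	SVTYPE=INS;SVLEN=50;TECOV=0.9	GT	1	1	0
chr1	9000	sv04	N	<INS>	.	PASS	SVTYPE=INS;SVLEN=51;TECOV=0.5	GT	1	1	0
chr1	11000	sv05	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-200;TECOV=0.49	GT	1	0	1
chr1	13000	sv06	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-200;TECOV=0.5	GT	1	1	0
chr1	15000	sv07	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-120;TECOV=1	GT	0	1	1
chr1	17000	sv08	N	<INS>	.	PASS	SVTYPE=INS;SVLEN=1000;TECOV=0.75	GT	1	1	0
chr1	19000	sv09	N	<INS>	.	PASS	SVTYPE=INS;SVLEN=300;TECOV=0	GT	1	0	1
chr1	21000	sv10	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-60;TECOV=0.6	GT	0	1	1
chr1	23000	sv11	N	<INS>	.	PASS	SVTYPE=INS;SVLEN=55;TECOV=0.51	GT	1	0	1
chr1	25000	sv12	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-5000;TECOV=0.95	GT	1	1	0
chr1	27000	sv13	N	<INS>	.	PASS	SVTYPE=INS;SVLEN=45;TECOV=0.45	GT	1	0	1
chr1	29000	sv14	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-80;TECOV=0.2	GT	0	1	1
chr1	31000	sv15	N	<INS>	.	PASS	SVTYPE=INS;SVLEN=52;TECOV=0.49	GT	1	0	1
chr1	33000	sv16	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-49;TECOV=0.5	GT	1	1	0
chr1	35000	sv17	N	<INS>	.	PASS	SVTYPE=INS;SVLEN=500;TECOV=0.66	GT	1	1	0
chr1	37000	sv18	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-75;TECOV=0.88	GT	0	1	1
chr1	39000	sv19	N	<INS>	.	PASS	SVTYPE=INS;SVLEN=51;TECOV=0.49	GT	1	0	1
chr1	41000	sv20	N	<DEL>	.	PASS	SVTYPE=DEL;SVLEN=-1200;TECOV=0.5	GT	0	1	1
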