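gene_id	symbol	biotype	chrom	start	end	strand
ENSG00000180139	ACTA2-AS1	lncRNA	chr1	1000000	1020000	+
ENSG00000223774	NA	lncRNA	chr1	2000000	2020000	+
ENSG00000230729	NA	lncRNA	chr1	3000000	3020000	+
ENSG00000230937	MIR205HG	lncRNA	chr1	4000000	4020000	+
ENSG00000234405	NA	lncRNA	chr1	5000000	5020000	+
ENSG00000234477	NA	lncRNA	chr1	6000000	6020000	+
ENSG00000234638	NA	lncRNA	chr1	7000000	7020000	+
ENSG00000249825	CTD-2201I18.1	lncRNA	chr5	79340000	79360000	+
ENSG00000255301	NA	lncRNA	chr1	9000000	9020000	+
ENSG00000258451	NA	lncRNA	chr1	10000000	10020000	+
ENSG00000259018	NA	lncRNA	chr1	11000000	11020000	+
ENSG00000259172	NA	lncRNA	chr15	101300000	101320000	+
ENSG00000259780	NA	lncRNA	chr1	13000000	13020000	+
ENSG00000260213	NA	lncRNA	chr1	14000000	14020000	+
ENSG00000261707	NA	lncRNA	chr1	15000000	15020000	+
ENSG00000263065	NA	lncRNA	chr1	16000000	16020000	+
ENSG00000263335	NA	lncRNA	chr1	17000000	17020000	+
ENSG00000267577	NA	lncRNA	chr1	18000000	18020000	+
ENSG00000267601	NA	lncRNA	chr1	19000000	19020000	+
ENSG00000271894	NA	lncRNA	chr1	20000000	20020000	+
ENSG00000279047	NA	lncRNA	chr1	21000000	21020000	+
ENSG00000145936	KCNMB1	mRNA	chr1	22000000	22020000	+
ENSG00000196923	PDLIM7	mRNA	chr1	23000000	23020000	+
ENSG00000140682	TGFB1I1	mRNA	chr1	24000000	24020000	+
ENSG00000198467	TPM2	mRNA	chr1	25000000	25020000	+
ENSG00000174099	MSRB3	mRNA	chr1	26000000	26020000	+
ENSG00000072864	NDE1	mRNA	chr1	27000000	27020000	+
ENSG00000168913	ENHO	mRNA	chr1	28000000	28020000	+
ENSG00000186081	KRT5	mRNA	chr1	29000000	29020000	+
ENSG00000172476	RAB40A	mRNA	chr1	30000000	30020000	+
ENSG00000108244	KRT23	mRNA	chr1	31000000	31020000	+
ENSG00000163017	ACTG2	mRNA	chr1	32000000	32020000	+
ENSG00000113296	THBS4	mRNA	chr5	79331165	79379982	-
ENSG00000186907	RTN4RL2	mRNA	chr1	34000000	34020000	+
ENSG00000258818	RNASE4	mRNA	chr1	35000000	35020000	+
ENSG00000100842	EFS	mRNA	chr1	36000000	36020000	+
ENSG00000140479	PCSK6	mRNA	chr15	101297201	101489344	-
ENSG00000167968	DNASE1L2	mRNA	chr1	38000000	38020000	+
ENSG00000166451	CENPN	mRNA	chr1	39000000	39020000	+
ENSG00000140876	NUDT7	mRNA	chr1	40000000	40020000	+
ENSG00000095637	SORBS1	mRNA	chr1	41000000	41020000	+
ENSG00000167646	DNAAF3	mRNA	chr1	42000000	42020000	+
ENSG00000178404	CEP295NL	mRNA	chr1	43000000	43020000	+
ENSG00000055813	CCDC85A	mRNA	chr1	44000000	44020000	+
ENSG00000112852	PCDHB2	mRNA	chr1	45000000	45020000	+
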