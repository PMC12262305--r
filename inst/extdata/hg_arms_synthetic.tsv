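kind	chrom	start	end	name
chrom	chr1	0	248960000	chr1
arm	chr1	0	123400000	1p
arm	chr1	123400000	248960000	1q
band	chr1	0	61700000	1p12
band	chr1	61700000	123400000	1p11
band	chr1	123400000	186180000	1q11
band	chr1	186180000	248960000	1q12
chrom	chr2	0	242190000	chr2
arm	chr2	0	93900000	2p
arm	chr2	93900000	242190000	2q
band	chr2	0	46950000	2p12
band	chr2	46950000	93900000	2p11
band	chr2	93900000	168045000	2q11
band	chr2	168045000	242190000	2q12
chrom	chr3	0	198300000	chr3
arm	chr3	0	90900000	3p
arm	chr3	90900000	198300000	3q
band	chr3	0	45450000	3p12
band	chr3	45450000	90900000	3p11
band	chr3	90900000	144600000	3q11
band	chr3	144600000	198300000	3q12
chrom	chr4	0	190210000	chr4
arm	chr4	0	5e+07	4p
arm	chr4	5e+07	190210000	4q
band	chr4	0	2.5e+07	4p12
band	chr4	2.5e+07	5e+07	4p11
band	chr4	5e+07	120105000	4q11
band	chr4	120105000	190210000	4q12
chrom	chr5	0	181540000	chr5
arm	chr5	0	48800000	5p
arm	chr5	48800000	181540000	5q
band	chr5	0	24400000	5p12
band	chr5	24400000	48800000	5p11
band	chr5	48800000	115170000	5q11
band	chr5	115170000	181540000	5q12
chrom	chr6	0	170810000	chr6
arm	chr6	0	59800000	6p
arm	chr6	59800000	170810000	6q
band	chr6	0	29900000	6p12
band	chr6	29900000	59800000	6p11
band	chr6	59800000	115305000	6q11
band	chr6	115305000	170810000	6q12
chrom	chr7	0	159350000	chr7
arm	chr7	0	60100000	7p
arm	chr7	60100000	159350000	7q
band	chr7	0	30050000	7p12
band	chr7	30050000	60100000	7p11
band	chr7	60100000	109725000	7q11
band	chr7	109725000	159350000	7q12
chrom	chr8	0	145140000	chr8
arm	chr8	0	45200000	8p
arm	chr8	45200000	145140000	8q
band	chr8	0	22600000	8p12
band	chr8	22600000	45200000	8p11
band	chr8	45200000	9e+07	8q11
band	chr8	9e+07	1.17e+08	8q21
band	chr8	1.17e+08	1.22e+08	8q22
band	chr8	1.22e+08	127300000	8q23
band	chr8	127300000	145140000	8q24
chrom	chr9	0	138390000	chr9
arm	chr9	0	4.3e+07	9p
arm	chr9	4.3e+07	138390000	9q
band	chr9	0	21500000	9p12
band	chr9	21500000	4.3e+07	9p11
band	chr9	4.3e+07	90695000	9q11
band	chr9	90695000	138390000	9q12
chrom	chr10	0	133800000	chr10
arm	chr10	0	39800000	10p
arm	chr10	39800000	133800000	10q
band	chr10	0	19900000	10p12
band	chr10	19900000	39800000	10p11
band	chr10	39800000	86800000	10q11
band	chr10	86800000	133800000	10q12
chrom	chr11	0	135090000	chr11
arm	chr11	0	53400000	11p
arm	chr11	53400000	135090000	11q
band	chr11	0	26700000	11p12
band	chr11	26700000	53400000	11p11
band	chr11	53400000	94245000	11q11
band	chr11	94245000	135090000	11q12
chrom	chr12	0	133280000	chr12
arm	chr12	0	35500000	12p
arm	chr12	35500000	133280000	12q
band	chr12	0	17750000	12p12
band	chr12	17750000	35500000	12p11
band	chr12	35500000	84390000	12q11
band	chr12	84390000	133280000	12q12
chrom	chr13	0	114360000	chr13
arm	chr13	0	17700000	13p
arm	chr13	17700000	114360000	13q
band	chr13	0	8850000	13p12
band	chr13	8850000	17700000	13p11
band	chr13	17700000	66030000	13q11
band	chr13	66030000	114360000	13q12
chrom	chr14	0	107040000	chr14
arm	chr14	0	17200000	14p
arm	chr14	17200000	107040000	14q
band	chr14	0	8600000	14p12
band	chr14	8600000	17200000	14p11
band	chr14	17200000	62120000	14q11
band	chr14	62120000	107040000	14q12
chrom	chr15	0	101990000	chr15
arm	chr15	0	1.9e+07	15p
arm	chr15	1.9e+07	101990000	15q
band	chr15	0	9500000	15p12
band	chr15	9500000	1.9e+07	15p11
band	chr15	1.9e+07	60495000	15q11
band	chr15	60495000	101990000	15q12
chrom	chr16	0	90340000	chr16
arm	chr16	0	36800000	16p
arm	chr16	36800000	90340000	16q
band	chr16	0	18400000	16p12
band	chr16	18400000	36800000	16p11
band	chr16	36800000	63570000	16q11
band	chr16	63570000	90340000	16q12
chrom	chr17	0	83260000	chr17
arm	chr17	0	25100000	17p
arm	chr17	25100000	83260000	17q
band	chr17	0	12550000	17p12
band	chr17	12550000	25100000	17p11
band	chr17	25100000	54180000	17q11
band	chr17	54180000	83260000	17q12
chrom	chr18	0	80370000	chr18
arm	chr18	0	18500000	18p
arm	chr18	18500000	80370000	18q
band	chr18	0	9250000	18p12
band	chr18	9250000	18500000	18p11
band	chr18	18500000	49435000	18q11
band	chr18	49435000	80370000	18q12
chrom	chr19	0	58620000	chr19
arm	chr19	0	26200000	19p
arm	chr19	26200000	58620000	19q
band	chr19	0	13100000	19p12
band	chr19	13100000	26200000	19p11
band	chr19	26200000	28500000	19q11
band	chr19	28500000	32900000	19q12
band	chr19	32900000	38500000	19q13.1
band	chr19	38500000	43100000	19q13.2
band	chr19	43100000	58620000	19q13.3
chrom	chr20	0	64440000	chr20
arm	chr20	0	28100000	20p
arm	chr20	28100000	64440000	20q
band	chr20	0	14050000	20p12
band	chr20	14050000	28100000	20p11
band	chr20	28100000	46270000	20q11
band	chr20	46270000	64440000	20q12
chrom	chr21	0	46710000	chr21
arm	chr21	0	1.2e+07	21p
arm	chr21	1.2e+07	46710000	21q
band	chr21	0	6e+06	21p12
band	chr21	6e+06	1.2e+07	21p11
band	chr21	1.2e+07	29355000	21q11
band	chr21	29355000	46710000	21q12
chrom	chr22	0	50820000	chr22
arm	chr22	0	1.5e+07	22p
arm	chr22	1.5e+07	50820000	22q
band	chr22	0	7500000	22p12
band	chr22	7500000	1.5e+07	22p11
band	chr22	1.5e+07	32910000	22q11
band	chr22	32910000	50820000	22q12
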