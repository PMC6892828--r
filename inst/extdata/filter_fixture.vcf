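##fileformat=VCFv4.2
##source=sweepscan_filter_fixture
##contig=<ID=1,length=600000>
##contig=<ID=2,length=600000>
##contig=<ID=X,length=600000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	AB1	AB2	AB3	BG1	BG2	BG3
1	10000	.	A	T	.	PASS	.	GT:DP	0/0:8	1/1:9	0/0:18	0/0:21	1/1:25	1/1:8
1	20000	.	A	T	.	PASS	.	GT:DP	1/1:12	1/1:16	1/1:21	1/1:12	0/0:12	1/1:9
1	30000	.	C	G	.	PASS	.	GT:DP	0/0:22	1/1:19	1/1:13	1/1:15	1/1:19	0/0:13
1	40000	.	C	G	.	PASS	.	GT:DP	1/1:21	0/0:13	1/1:8	1/1:15	0/1:13	0/0:19
1	50000	.	T	A	.	PASS	.	GT:DP	1/1:21	0/0:14	0/0:20	0/0:19	1/1:23	1/1:8
1	60000	.	C	G	.	PASS	.	GT:DP	0/0:23	0/0:18	1/1:17	0/0:14	0/0:9	0/0:17
1	70000	.	T	A,C	.	PASS	.	GT:DP	0/1:14	0/0:15	0/0:8	1/1:10	1/1:18	1/1:8
1	80000	.	C	A	.	PASS	.	GT:DP	1/1:10	0/0:10	0/0:14	0/0:21	0/0:10	0/0:19
1	90000	.	G	T	.	PASS	.	GT:DP	0/0:14	0/0:22	0/0:23	1/1:11	0/0:9	0/0:23
1	1e+05	.	C	G	.	PASS	.	GT:DP	0/0:24	0/0:9	1/1:18	0/0:10	1/1:10	0/0:21
1	110000	.	C	G	.	PASS	.	GT:DP	1/1:22	1/1:12	0/1:12	1/1:14	0/0:12	0/0:19
1	120000	.	C	A	.	PASS	.	GT:DP	1/1:2	0/0:2	1/1:2	1/1:2	1/1:2	1/1:2
1	130000	.	C	G	.	PASS	.	GT:DP	0/1:17	1/1:13	0/0:25	0/0:23	1/1:9	0/0:15
1	140000	.	A	G	.	PASS	.	GT:DP	0/0:11	0/0:16	1/1:16	0/0:22	1/1:13	0/1:13
1	150000	.	G	A	.	PASS	.	GT:DP	0/1:21	1/1:12	0/0:14	0/0:17	0/0:15	0/0:8
1	160000	.	A	C	.	PASS	.	GT:DP	1/1:19	0/0:22	0/0:21	0/0:22	0/1:24	0/0:22
1	170000	.	G	T	.	PASS	.	GT:DP	0/0:25	0/0:16	1/1:9	0/0:12	0/1:18	1/1:9
1	180000	.	G	T	.	PASS	.	GT:DP	0/0:12	1/1:21	0/0:12	0/0:18	0/0:18	0/0:24
1	190000	.	T	A	.	PASS	.	GT:DP	1/1:14	0/0:13	0/1:23	1/1:9	1/1:20	0/0:10
1	2e+05	.	G	T	.	PASS	.	GT:DP	0/0:20	0/0:25	0/0:12	0/0:23	0/0:15	0/0:9
1	210000	.	T	A	.	PASS	.	GT:DP	0/1:13	0/0:24	1/1:16	0/0:20	1/1:21	1/1:16
1	220000	.	G	A	.	PASS	.	GT:DP	1/1:8	0/0:15	1/1:12	1/1:17	1/1:19	1/1:10
1	230000	.	G	C	.	PASS	.	GT:DP	1/1:16	0/0:19	0/0:25	0/0:19	1/1:14	0/0:11
1	240000	.	A	C	.	PASS	.	GT:DP	0/0:22	0/1:12	0/0:21	0/0:14	0/0:20	1/1:22
1	250000	.	C	A	.	PASS	.	GT:DP	0/0:20	1/1:15	0/0:9	0/1:16	./.:.	0/0:21
1	260000	.	C	A	.	PASS	.	GT:DP	1/1:12	1/1:12	1/1:15	0/1:20	0/0:11	0/0:17
1	270000	.	A	C	.	PASS	.	GT:DP	1/1:23	0/1:22	1/1:23	1/1:24	1/1:21	0/0:13
1	280000	.	A	T	.	PASS	.	GT:DP	1/1:25	0/0:21	1/1:20	1/1:22	0/0:9	1/1:20
1	290000	.	C	A	.	PASS	.	GT:DP	0/0:13	0/0:23	0/0:19	1/1:17	0/0:8	0/0:13
1	3e+05	.	G	A	.	PASS	.	GT:DP	0/0:13	0/0:19	0/0:10	0/0:11	1/1:22	1/1:21
1	310000	.	T	C	.	PASS	.	GT:DP	0/0:21	0/1:23	1/1:12	1/1:10	1/1:11	0/0:24
1	320000	.	A	T	.	PASS	.	GT:DP	1/1:12	0/0:18	0/0:19	1/1:18	0/1:13	0/0:23
1	330000	.	G	C,A	.	PASS	.	GT:DP	1/1:24	1/1:16	1/1:25	0/0:19	1/1:15	1/1:13
1	340000	.	G	C	.	PASS	.	GT:DP	1/1:17	1/1:15	0/0:10	0/1:18	1/1:20	1/1:9
1	350000	.	A	C	.	PASS	.	GT:DP	1/1:12	0/0:17	0/0:9	0/0:12	1/1:21	1/1:13
1	360000	.	T	G	.	PASS	.	GT:DP	0/0:24	0/0:23	0/0:24	1/1:12	0/0:8	0/1:8
1	370000	.	C	T	.	PASS	.	GT:DP	0/0:25	0/0:10	0/0:9	0/1:22	1/1:17	1/1:20
1	380000	.	G	C	.	PASS	.	GT:DP	0/0:8	0/0:11	1/1:12	0/0:21	0/0:11	0/0:9
1	390000	.	T	G	.	PASS	.	GT:DP	0/0:16	1/1:15	0/1:8	0/0:24	0/0:19	0/0:10
1	4e+05	.	A	C	.	PASS	.	GT:DP	0/0:21	0/0:23	0/0:19	1/1:19	0/0:21	0/0:23
1	410000	.	T	C	.	PASS	.	GT:DP	1/1:12	1/1:19	1/1:16	0/0:9	0/0:16	1/1:16
1	420000	.	C	G	.	PASS	.	GT:DP	1/1:9	1/1:10	1/1:8	1/1:9	0/0:12	1/1:9
1	430000	.	C	A	.	PASS	.	GT:DP	1/1:14	1/1:11	0/0:13	1/1:25	1/1:23	1/1:20
1	440000	.	C	G	.	PASS	.	GT:DP	0/0:15	0/0:10	1/1:15	1/1:12	0/0:21	0/0:20
1	450000	.	G	A	.	PASS	.	GT:DP	0/0:35	1/1:35	1/1:35	0/0:35	0/1:35	1/1:35
1	460000	.	C	T	.	PASS	.	GT:DP	0/0:21	0/0:22	0/0:22	0/0:17	0/0:12	1/1:8
1	470000	.	A	C	.	PASS	.	GT:DP	0/0:8	1/1:17	0/0:20	1/1:15	0/0:19	1/1:18
1	480000	.	C	A	.	PASS	.	GT:DP	0/0:12	1/1:12	0/0:11	0/1:18	0/0:16	0/0:9
1	490000	.	A	T	.	PASS	.	GT:DP	0/0:12	1/1:24	0/0:16	0/0:19	0/0:20	1/1:19
1	5e+05	.	C	G	.	PASS	.	GT:DP	0/0:14	0/0:12	0/0:14	1/1:14	0/0:19	0/1:19
2	10000	.	T	A	.	PASS	.	GT:DP	0/0:10	0/0:23	1/1:14	0/0:17	0/0:10	1/1:20
2	20000	.	G	T	.	PASS	.	GT:DP	1/1:14	0/0:19	0/1:15	0/0:20	0/0:25	0/0:17
2	30000	.	T	A	.	PASS	.	GT:DP	0/0:13	1/1:15	1/1:20	1/1:18	1/1:20	0/1:9
2	40000	.	T	A	.	PASS	.	GT:DP	1/1:19	1/1:20	1/1:14	0/0:10	0/0:12	1/1:22
2	50000	.	G	A	.	PASS	.	GT:DP	1/1:25	0/1:14	1/1:21	1/1:17	1/1:23	0/0:8
2	60000	.	T	A	.	PASS	.	GT:DP	0/0:12	0/1:17	1/1:11	0/0:19	1/1:12	1/1:24
2	70000	.	A	C	.	PASS	.	GT:DP	1/1:13	1/1:19	1/1:17	0/0:11	1/1:25	1/1:11
2	80000	.	C	T	.	PASS	.	GT:DP	1/1:11	0/0:10	0/0:23	0/1:10	0/0:16	1/1:11
2	90000	.	G	T	.	PASS	.	GT:DP	1/1:18	1/1:25	1/1:25	0/0:9	1/1:14	0/1:21
2	1e+05	.	T	G	.	PASS	.	GT:DP	1/1:3	0/1:3	1/1:3	1/1:3	1/1:3	0/0:3
2	110000	.	G	C	.	PASS	.	GT:DP	1/1:16	0/0:22	0/0:20	0/0:12	0/0:10	0/0:21
2	120000	.	C	T	.	PASS	.	GT:DP	1/1:23	0/0:11	1/1:21	1/1:18	1/1:20	1/1:23
2	130000	.	G	C	.	PASS	.	GT:DP	1/1:16	0/0:17	0/0:21	0/0:13	0/1:12	0/0:25
2	140000	.	T	C	.	PASS	.	GT:DP	1/1:18	1/1:20	0/0:13	1/1:14	0/1:12	1/1:24
2	150000	.	G	C	.	PASS	.	GT:DP	1/1:21	0/0:18	0/0:23	1/1:21	0/1:16	0/0:8
2	160000	.	T	A	.	PASS	.	GT:DP	1/1:17	1/1:8	1/1:15	1/1:24	0/0:20	1/1:20
2	170000	.	A	G	.	PASS	.	GT:DP	0/0:13	1/1:25	0/0:10	0/0:24	0/0:8	0/0:23
2	180000	.	C	G	.	PASS	.	GT:DP	1/1:24	1/1:21	0/0:22	0/1:8	1/1:24	1/1:14
2	190000	.	T	G	.	PASS	.	GT:DP	1/1:13	1/1:22	1/1:15	0/0:22	0/0:17	1/1:10
2	2e+05	.	T	C	.	PASS	.	GT:DP	0/0:15	0/0:23	1/1:20	0/0:16	0/0:22	0/1:10
2	210000	.	G	T,C	.	PASS	.	GT:DP	1/1:12	1/1:8	0/0:24	0/1:23	0/0:8	0/0:23
2	220000	.	T	G	.	PASS	.	GT:DP	1/1:10	1/1:16	1/1:12	0/1:18	1/1:22	0/0:12
2	230000	.	C	T	.	PASS	.	GT:DP	0/0:12	1/1:21	1/1:24	1/1:16	1/1:16	0/0:22
2	240000	.	G	C	.	PASS	.	GT:DP	0/0:19	0/0:24	0/1:9	0/0:24	1/1:17	1/1:25
2	250000	.	A	G	.	PASS	.	GT:DP	1/1:19	1/1:21	1/1:22	1/1:18	0/0:9	1/1:11
2	260000	.	G	T	.	PASS	.	GT:DP	1/1:12	0/0:21	1/1:12	0/0:14	1/1:22	1/1:21
2	270000	.	T	G	.	PASS	.	GT:DP	0/0:20	0/0:13	0/0:20	1/1:17	0/0:14	0/0:20
2	280000	.	C	A	.	PASS	.	GT:DP	1/1:17	1/1:12	0/0:24	1/1:8	0/0:15	1/1:9
2	290000	.	C	A	.	PASS	.	GT:DP	0/0:9	0/0:8	0/0:12	0/1:8	1/1:10	1/1:13
2	3e+05	.	T	G	.	PASS	.	GT:DP	1/1:24	1/1:8	1/1:25	1/1:16	1/1:18	1/1:9
2	310000	.	G	T	.	PASS	.	GT:DP	1/1:21	0/0:8	1/1:19	0/0:10	0/1:9	0/0:14
2	320000	.	T	C	.	PASS	.	GT:DP	1/1:9	1/1:12	1/1:20	0/0:12	0/0:15	1/1:13
2	330000	.	C	A	.	PASS	.	GT:DP	0/0:23	1/1:13	1/1:18	1/1:19	0/0:16	0/1:16
2	340000	.	G	A	.	PASS	.	GT:DP	1/1:15	1/1:20	0/0:15	1/1:18	0/1:22	1/1:11
2	350000	.	A	C	.	PASS	.	GT:DP	1/1:22	0/0:21	0/0:14	1/1:21	0/0:24	0/0:18
2	360000	.	A	G	.	PASS	.	GT:DP	0/0:20	0/1:13	1/1:25	0/0:10	0/0:23	0/0:18
2	370000	.	T	G	.	PASS	.	GT:DP	0/0:23	1/1:8	1/1:23	0/0:17	1/1:11	1/1:17
2	380000	.	G	T	.	PASS	.	GT:DP	0/0:24	1/1:8	0/0:14	0/0:13	1/1:11	1/1:20
2	390000	.	G	C	.	PASS	.	GT:DP	0/0:22	1/1:15	1/1:18	1/1:10	1/1:20	0/1:9
2	4e+05	.	G	T	.	PASS	.	GT:DP	1/1:15	1/1:8	1/1:15	1/1:16	./.:.	0/0:22
2	410000	.	C	T	.	PASS	.	GT:DP	0/0:14	1/1:16	0/0:22	1/1:22	0/0:16	0/0:22
2	420000	.	T	C	.	PASS	.	GT:DP	0/0:22	0/0:20	0/0:13	1/1:22	0/0:17	1/1:18
2	430000	.	A	G	.	PASS	.	GT:DP	0/0:16	0/1:21	1/1:25	0/0:17	0/0:13	1/1:9
2	440000	.	G	C	.	PASS	.	GT:DP	0/0:25	0/0:11	0/1:23	0/0:20	0/0:8	1/1:23
2	450000	.	C	A	.	PASS	.	GT:DP	1/1:25	1/1:9	1/1:12	0/0:25	0/1:12	0/0:17
2	460000	.	A	C	.	PASS	.	GT:DP	1/1:21	0/0:15	0/1:9	0/0:20	0/0:18	0/0:16
2	470000	.	C	A	.	PASS	.	GT:DP	1/1:19	1/1:14	0/0:9	0/0:20	1/1:18	0/0:14
2	480000	.	G	A	.	PASS	.	GT:DP	0/0:9	0/0:16	0/0:23	0/0:24	1/1:20	1/1:17
X	10000	.	G	T	.	PASS	.	GT:DP	1/1:10	1/1:20	1/1:16	1/1:10	0/0:24	1/1:21
X	20000	.	T	C	.	PASS	.	GT:DP	1/1:15	0/1:12	0/0:21	1/1:20	1/1:16	1/1:20
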