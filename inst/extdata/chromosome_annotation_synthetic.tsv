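chromosome	coding_genes	length_mbp
1	3946	249.25
2	2918	243.2
3	2079	198
4	1530	191.2
5	1719	180.9
6	2053	171.1
7	1830	159.1
8	1391	146.4
9	1483	141.2
10	1490	135.5
11	2362	135
12	1875	133.9
13	691	115.2
14	1180	107.3
15	1281	102.5
16	1541	90.4
17	1966	81.2
18	640	78
19	2191	59.1
20	1008	63
21	481	48.1
22	872	51.3
X	1475	155.3
Y	148	59.4
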