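gene	chrom	copy_limit
SYNDSG0101	chr1	3
SYNDSG0102	chr1	20
SYNDSG0103	chr1	2
SYNDSG0104	chr1	2
SYNDSG0105	chr1	10
SYNDSG0106	chr1	10
SYNDSG0107	chr1	50
SYNDSG0108	chr1	3
SYNDSG0201	chr2	3
SYNDSG0202	chr2	3
SYNDSG0203	chr2	3
SYNDSG0204	chr2	2
SYNDSG0205	chr2	100
SYNDSG0206	chr2	10
SYNDSG0207	chr2	2
SYNDSG0208	chr2	20
SYNDSG0209	chr2	1
SYNDSG0301	chr3	20
SYNDSG0302	chr3	10
SYNDSG0303	chr3	50
SYNDSG0304	chr3	5
SYNDSG0401	chr4	1
SYNDSG0402	chr4	10
SYNDSG0403	chr4	3
SYNDSG0404	chr4	3
SYNDSG0405	chr4	5
SYNDSG0406	chr4	2
SYNDSG0407	chr4	100
SYNDSG0501	chr5	3
SYNDSG0502	chr5	3
SYNDSG0503	chr5	2
SYNDSG0504	chr5	10
SYNDSG0505	chr5	2
SYNDSG0506	chr5	2
SYNDSG0601	chr6	10
SYNDSG0602	chr6	5
SYNDSG0603	chr6	1
SYNDSG0604	chr6	3
SYNDSG0605	chr6	20
SYNDSG0701	chr7	2
SYNDSG0702	chr7	5
SYNDSG0703	chr7	5
SYNDSG0704	chr7	2
SYNDSG0705	chr7	3
SYNDSG0706	chr7	2
SYNDSG0801	chr8	5
SYNDSG0802	chr8	3
SYNDSG0803	chr8	2
SYNDSG0901	chr9	5
SYNDSG0902	chr9	5
SYNDSG0903	chr9	20
SYNDSG0904	chr9	20
SYNDSG0905	chr9	10
SYNDSG0906	chr9	3
SYNDSG1001	chr10	1
SYNDSG1002	chr10	1
SYNDSG1003	chr10	5
SYNDSG1004	chr10	3
SYNDSG1005	chr10	20
SYNDSG1006	chr10	10
SYNDSG1101	chr11	100
SYNDSG1102	chr11	3
SYNDSG1103	chr11	10
SYNDSG1104	chr11	50
SYNDSG1105	chr11	2
SYNDSG1201	chr12	3
SYNDSG1202	chr12	100
SYNDSG1203	chr12	10
SYNDSG1204	chr12	3
SYNDSG1205	chr12	100
SYNDSG1206	chr12	5
SYNDSG1301	chr13	2
SYNDSG1302	chr13	2
SYNDSG1303	chr13	10
SYNDSG1304	chr13	1
SYNDSG1305	chr13	2
SYNDSG1306	chr13	3
SYNDSG1307	chr13	10
SYNDSG1308	chr13	5
SYNDSG1309	chr13	10
SYNDSG1401	chr14	3
SYNDSG1402	chr14	3
SYNDSG1403	chr14	10
SYNDSG1501	chr15	3
SYNDSG1502	chr15	5
SYNDSG1503	chr15	20
SYNDSG1504	chr15	2
SYNDSG1505	chr15	50
SYNDSG1601	chr16	3
SYNDSG1602	chr16	5
SYNDSG1603	chr16	2
SYNDSG1604	chr16	5
SYNDSG1605	chr16	100
SYNDSG1606	chr16	1
SYNDSG1607	chr16	100
SYNDSG1608	chr16	10
SYNDSG1609	chr16	10
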