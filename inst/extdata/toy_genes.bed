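11	47350000	47380000	SPI1	0	+
11	47419500	47430000	MTCH2	0	-
11	47430500	47440000	SLC39A13	0	+
11	47440500	47455000	PSMC3	0	-
11	47459000	47470000	RAPSN	0	+
11	47530000	47585000	CELF1	0	-
11	47585500	47595000	PTPMT1	0	+
11	47600000	47610000	NDUFS3	0	-
11	47604000	47608000	FAM180B	0	+
11	47700000	47760000	AGBL2	0	-
1	1000	2000	GENEA	0	+
1	5000	6000	GENEB	0	-
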