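# Default human rRNA 2'-O-methylation site catalog (104 sites).
# SYNTHETIC placeholders: only eleven coordinates are documented mature-rRNA
# positions (SSU-A99, SSU-G436, SSU-C797, SSU-G867, SSU-C1272, LSU-G1303,
# LSU-A2388, LSU-G2411, LSU-C3680, LSU-G3723, LSU-G4588) with guides SNORD57,
# SNORD87 and SNORD88A/B/C where documented. All other positions, nucleotides
# and any guide name beginning 'SNORDX' are deterministic placeholders that
# make the catalog a realistic size; they are NOT biological truth.
# Coordinates: 1-based on mature 18S (1869 nt) and 28S (5070 nt) rRNA.
subunit	position	nucleotide	label	guides
18S	40	U	SSU-U40	
18S	51	C	SSU-C51	
18S	99	A	SSU-A99	SNORD57
18S	141	C	SSU-C141	
18S	225	U	SSU-U225	
18S	245	C	SSU-C245	
18S	287	A	SSU-A287	
18S	343	U	SSU-U343	
18S	420	C	SSU-C420	
18S	436	G	SSU-G436	SNORDX436
18S	458	C	SSU-C458	
18S	479	U	SSU-U479	
18S	520	G	SSU-G520	
18S	674	A	SSU-A674	
18S	797	C	SSU-C797	SNORDX797
18S	812	A	SSU-A812	
18S	858	A	SSU-A858	
18S	867	G	SSU-G867	SNORDX867
18S	896	A	SSU-A896	
18S	909	G	SSU-G909	
18S	926	C	SSU-C926	
18S	953	C	SSU-C953	
18S	1022	A	SSU-A1022	
18S	1079	G	SSU-G1079	
18S	1141	C	SSU-C1141	
18S	1213	A	SSU-A1213	
18S	1234	U	SSU-U1234	
18S	1272	C	SSU-C1272	SNORDX1272
18S	1342	G	SSU-G1342	
18S	1397	C	SSU-C1397	
18S	1409	G	SSU-G1409	
18S	1449	C	SSU-C1449	
18S	1476	U	SSU-U1476	
18S	1538	C	SSU-C1538	
18S	1601	U	SSU-U1601	
18S	1613	G	SSU-G1613	
18S	1630	G	SSU-G1630	
18S	1671	A	SSU-A1671	
18S	1711	G	SSU-G1711	
18S	1758	U	SSU-U1758	
18S	1804	U	SSU-U1804	
18S	1813	A	SSU-A1813	
28S	54	A	LSU-A54	
28S	77	U	LSU-U77	
28S	96	A	LSU-A96	
28S	182	U	LSU-U182	
28S	190	A	LSU-A190	
28S	265	C	LSU-C265	
28S	560	C	LSU-C560	
28S	573	C	LSU-C573	
28S	660	A	LSU-A660	
28S	707	G	LSU-G707	
28S	717	A	LSU-A717	
28S	800	U	LSU-U800	
28S	841	C	LSU-C841	
28S	947	G	LSU-G947	
28S	972	U	LSU-U972	
28S	986	A	LSU-A986	
28S	1092	A	LSU-A1092	
28S	1161	U	LSU-U1161	
28S	1239	U	LSU-U1239	
28S	1303	G	LSU-G1303	SNORDX1303
28S	1318	C	LSU-C1318	
28S	1335	U	LSU-U1335	
28S	1362	C	LSU-C1362	
28S	1624	A	LSU-A1624	
28S	1646	U	LSU-U1646	
28S	1656	U	LSU-U1656	
28S	1769	C	LSU-C1769	
28S	1967	A	LSU-A1967	
28S	2049	G	LSU-G2049	
28S	2103	A	LSU-A2103	
28S	2206	A	LSU-A2206	
28S	2236	C	LSU-C2236	
28S	2249	G	LSU-G2249	
28S	2388	A	LSU-A2388	SNORDX2388
28S	2403	G	LSU-G2403	
28S	2411	G	LSU-G2411	SNORDX2411
28S	2700	G	LSU-G2700	
28S	2745	A	LSU-A2745	
28S	2892	U	LSU-U2892	
28S	2907	U	LSU-U2907	
28S	2918	U	LSU-U2918	
28S	3175	A	LSU-A3175	
28S	3368	C	LSU-C3368	
28S	3397	U	LSU-U3397	
28S	3550	C	LSU-C3550	
28S	3680	C	LSU-C3680	SNORD88A/B/C
28S	3723	G	LSU-G3723	SNORD87
28S	3819	G	LSU-G3819	
28S	3897	G	LSU-G3897	
28S	3915	A	LSU-A3915	
28S	4078	C	LSU-C4078	
28S	4216	C	LSU-C4216	
28S	4310	G	LSU-G4310	
28S	4418	G	LSU-G4418	
28S	4432	A	LSU-A4432	
28S	4588	G	LSU-G4588	SNORDX4588
28S	4759	C	LSU-C4759	
28S	4768	A	LSU-A4768	
28S	4782	G	LSU-G4782	
28S	4893	G	LSU-G4893	
28S	4981	A	LSU-A4981	
28S	5041	C	LSU-C5041	
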