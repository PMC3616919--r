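gene	m_c3_6	p_c3_6	m_c7	p_c7	m_c8	p_c8	size_nt	introns	note
luna	6	6	12	7	13	9	128861	5
CG16813	2	7	6	5	24	22	996	0
zen	25	0	12	0	88	83	1336	1
CG14014			6	24	653	452	1127	0
Brd			9	16	291	382	530	0
bnk			15	15	607	563	1572	0
sisA			9	13	47	53	768	0
CG15480			24	12	153	152	501	0
CG18269			7	9	70	93	603	0
pn			0	6	3	1	1846	1	overlaps_Nmd3
CG15876			7	5	61	51	619	0
CG8960			8	2	663	275	646	0	not_annotated
amos			20	2	164	124	820	0	not_annotated
sc			5	1	112	77	1483	0
Bro			8	0	374	213	745	0
SNCF					199	109	613	0
run					229	162	2881	1
m4					174	121	733	0
CG13716					65	54	354	0
l(1)sc					37	29	1095	0
CG14427					92	36	1162	0
CG13000					123	54	466	0	not_annotated
scw					105	88	1409	0
eve					153	249	1583	1
esg					151	95	2277	0
scw					8	9	1409	0
odd					5	7	2000	1	not_annotated
Egfr					12	3	36.4	5
Cpr67B					5	7	1378	1
w-cup					9	1	1933	1
CG32532			35	1	7	8	15471	8	single_500bp_region
roX1					15	6	3748	1
CG7778					9	3	1079	1	not_annotated
h					118	130	3285	2
CG4440					36	15	352	1	not_annotated
CG15479					10	11	602	0	not_annotated
CG7203					6	2	989	1
Bsg25A					37	39	1600	0	not_annotated
Z600					4	1	300	0	not_annotated
noc					28	8	3158	1
sog					23	6	21971	4
Cyp4g1					4	2	2277	0
tld					30	22	3778	6
Prm					5	1	7531	2	not_annotated
gk					11	5	6071	2
hkb					5	4	1628	1
CG14915					16	20	506	0
spo					22	21	2495	0
tll					58	39	2059	1
Kr					25	29	2918	1
Pepck					76	15	1845	0
term					32	6	1463	0
sna					29	25	1677	0
fd19B					32	22	783	0
CG3332					5	6	4740	7
ftz					21	29	1904	1
CG14317					68	37	1347	0
CG13711					89	38	743	0
gt					120	72	1857	1
Doc1					10	2	3668	5
CG13427					592	157	438	0
inx3					5	6	5075	5
CG15634					195	178	1444	0
CG34214					15	6	594	1
Notum					5	2	9273	3
axo					3	3	57714	25
slp1					48	47	1458	0
D					10	2	1711	0
CG5973					9	1	7764	0
Ocho					44	29	759	0
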