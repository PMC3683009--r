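gene	chrom
ABCA4	1
USH2A	1
NMNAT1	1
RP1	8
CNGB3	8
CHM	X
RDGP001	1
RDGP002	2
RDGP003	3
RDGP004	4
RDGP005	5
RDGP006	6
RDGP007	7
RDGP008	8
RDGP009	9
RDGP010	10
RDGP011	11
RDGP012	12
RDGP013	13
RDGP014	14
RDGP015	15
RDGP016	16
RDGP017	17
RDGP018	18
RDGP019	19
RDGP020	20
RDGP021	21
RDGP022	22
RDGP023	1
RDGP024	2
RDGP025	3
RDGP026	4
RDGP027	5
RDGP028	6
RDGP029	7
RDGP030	8
RDGP031	9
RDGP032	10
RDGP033	11
RDGP034	12
RDGP035	13
RDGP036	14
RDGP037	15
RDGP038	16
RDGP039	17
RDGP040	18
RDGP041	19
RDGP042	20
RDGP043	21
RDGP044	22
RDGP045	1
RDGP046	2
RDGP047	3
RDGP048	4
RDGP049	5
RDGP050	6
RDGP051	7
RDGP052	8
RDGP053	9
RDGP054	10
RDGP055	11
RDGP056	12
RDGP057	13
RDGP058	14
RDGP059	15
RDGP060	16
RDGP061	17
RDGP062	18
RDGP063	19
RDGP064	20
RDGP065	21
RDGP066	22
RDGP067	1
RDGP068	2
RDGP069	3
RDGP070	4
RDGP071	5
RDGP072	6
RDGP073	7
RDGP074	8
RDGP075	9
RDGP076	10
RDGP077	11
RDGP078	12
RDGP079	13
RDGP080	14
RDGP081	15
RDGP082	16
RDGP083	17
RDGP084	18
RDGP085	19
RDGP086	20
RDGP087	21
RDGP088	22
RDGP089	1
RDGP090	2
RDGP091	3
RDGP092	4
RDGP093	5
RDGP094	6
RDGP095	7
RDGP096	8
RDGP097	9
RDGP098	10
RDGP099	11
RDGP100	12
RDGP101	13
RDGP102	14
RDGP103	15
RDGP104	16
RDGP105	17
RDGP106	18
RDGP107	19
RDGP108	20
RDGP109	21
RDGP110	22
RDGP111	1
RDGP112	2
RDGP113	3
RDGP114	4
RDGP115	5
RDGP116	6
RDGP117	7
RDGP118	8
RDGP119	9
RDGP120	10
RDGP121	11
RDGP122	12
RDGP123	13
RDGP124	14
RDGP125	15
RDGP126	16
RDGP127	17
RDGP128	18
RDGP129	19
RDGP130	20
RDGP131	21
RDGP132	22
RDGP133	1
RDGP134	2
RDGP135	3
RDGP136	4
RDGP137	5
RDGP138	6
RDGP139	7
RDGP140	8
RDGP141	9
RDGP142	10
RDGP143	11
RDGP144	12
RDGP145	13
RDGP146	14
RDGP147	15
RDGP148	16
RDGP149	17
RDGP150	18
RDGP151	X
RDGP152	X
RDGP153	X
RDGP154	X
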