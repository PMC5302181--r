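snp	Q1	Q5
snp0000001	1	1
snp0000002	1	0
snp0000003	0	0
snp0000004	0	1
snp0000005	1	0
snp0000006	0	0
snp0000007	0	0
snp0000008	1	1
snp0000009	0	1
snp0000010	1	0
snp0000011	0	0
snp0000012	1	0
snp0000013	0	0
snp0000014	1	0
snp0000015	0	1
snp0000016	0	0
snp0000017	1	0
snp0000018	0	0
snp0000019	0	0
snp0000020	0	0
snp0000021	0	0
snp0000022	0	0
snp0000023	0	0
snp0000024	0	0
snp0000025	0	0
snp0000026	0	1
snp0000027	0	0
snp0000028	0	0
snp0000029	0	0
snp0000030	1	0
snp0000031	1	0
snp0000032	0	0
snp0000033	1	0
snp0000034	0	0
snp0000035	1	1
snp0000036	0	0
snp0000037	0	1
snp0000038	0	0
snp0000039	1	0
snp0000040	0	1
snp0000041	0	1
snp0000042	1	0
snp0000043	0	1
snp0000044	0	1
snp0000045	0	0
snp0000046	0	0
snp0000047	1	1
snp0000048	0	0
snp0000049	1	0
snp0000050	0	0
snp0000051	1	0
snp0000052	1	0
snp0000053	1	0
snp0000054	1	0
snp0000055	1	0
snp0000056	1	0
snp0000057	1	0
snp0000058	0	1
snp0000059	1	1
snp0000060	0	0
snp0000061	0	0
snp0000062	1	0
snp0000063	1	1
snp0000064	0	0
snp0000065	0	0
snp0000066	0	0
snp0000067	1	0
snp0000068	0	0
snp0000069	1	0
snp0000070	1	0
snp0000071	1	0
snp0000072	0	0
snp0000073	1	0
snp0000074	1	0
snp0000075	0	0
snp0000076	1	0
snp0000077	1	1
snp0000078	1	0
snp0000079	0	0
snp0000080	1	0
snp0000081	0	0
snp0000082	1	0
snp0000083	1	0
snp0000084	1	0
snp0000085	0	1
snp0000086	1	0
snp0000087	1	0
snp0000088	1	0
snp0000089	0	1
snp0000090	0	0
snp0000091	1	0
snp0000092	1	1
snp0000093	1	0
snp0000094	0	1
snp0000095	0	0
snp0000096	0	0
snp0000097	1	0
snp0000098	0	0
snp0000099	1	0
snp0000100	0	0
snp0000101	0	0
snp0000102	1	0
snp0000103	0	0
snp0000104	0	0
snp0000105	0	1
snp0000106	0	0
snp0000107	1	0
snp0000108	1	0
snp0000109	0	0
snp0000110	1	1
snp0000111	0	1
snp0000112	1	0
snp0000113	0	0
snp0000114	0	0
snp0000115	0	0
snp0000116	0	1
snp0000117	1	0
snp0000118	0	0
snp0000119	0	0
snp0000120	1	0
snp0000121	0	1
snp0000122	0	0
snp0000123	1	0
snp0000124	1	1
snp0000125	0	0
snp0000126	0	0
snp0000127	0	0
snp0000128	0	0
snp0000129	0	0
snp0000130	0	0
snp0000131	0	0
snp0000132	1	0
snp0000133	0	0
snp0000134	0	1
snp0000135	1	0
snp0000136	0	1
snp0000137	0	0
snp0000138	1	0
snp0000139	1	0
snp0000140	0	0
snp0000141	1	0
snp0000142	0	0
snp0000143	1	0
snp0000144	1	0
snp0000145	1	1
snp0000146	0	0
snp0000147	0	0
snp0000148	1	0
snp0000149	1	0
snp0000150	0	0
snp0000151	0	0
snp0000152	0	1
snp0000153	1	0
snp0000154	1	0
snp0000155	1	0
snp0000156	1	1
snp0000157	0	1
snp0000158	1	0
snp0000159	1	0
snp0000160	0	0
snp0000161	0	0
snp0000162	1	0
snp0000163	1	1
snp0000164	0	0
snp0000165	0	0
snp0000166	0	0
snp0000167	0	1
snp0000168	0	1
snp0000169	0	0
snp0000170	0	1
snp0000171	1	0
snp0000172	1	0
snp0000173	0	1
snp0000174	1	0
snp0000175	0	0
snp0000176	1	0
snp0000177	1	0
snp0000178	1	0
snp0000179	1	0
snp0000180	1	0
snp0000181	0	0
snp0000182	0	1
snp0000183	1	0
snp0000184	1	0
snp0000185	0	1
snp0000186	0	0
snp0000187	1	0
snp0000188	0	0
snp0000189	0	0
snp0000190	0	0
snp0000191	0	1
snp0000192	0	0
snp0000193	0	0
snp0000194	1	0
snp0000195	0	0
snp0000196	0	0
snp0000197	0	0
snp0000198	1	0
snp0000199	1	0
snp0000200	0	0
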