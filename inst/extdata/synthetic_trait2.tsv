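snp	beta	se
snp0000001	-0.439295	0.0619026
snp0000002	-0.00705879	0.0349052
snp0000003	-0.0382379	0.0291555
snp0000004	-0.0395227	0.028432
snp0000005	0.0286129	0.0297388
snp0000006	-0.0101623	0.0570483
snp0000007	9.30592e-05	0.0282889
snp0000008	0.0147231	0.0287778
snp0000009	-0.0138068	0.0302741
snp0000010	-0.00662548	0.0314146
snp0000011	0.517975	0.0310172
snp0000012	-0.0115911	0.0328046
snp0000013	-0.0298516	0.0284394
snp0000014	0.0224499	0.0284757
snp0000015	-0.200123	0.02892
snp0000016	-0.0240367	0.0305901
snp0000017	0.0564792	0.0317013
snp0000018	-0.00729546	0.0291902
snp0000019	-0.00957805	0.0318105
snp0000020	-0.045412	0.0302881
snp0000021	0.00105582	0.030867
snp0000022	-0.0265816	0.029177
snp0000023	0.0156346	0.044494
snp0000024	0.0069006	0.0353127
snp0000025	0.0244302	0.0284194
snp0000026	-0.0191523	0.0284093
snp0000027	-0.0608601	0.0366057
snp0000028	0.0110641	0.028366
snp0000029	0.0150051	0.0339969
snp0000030	0.0377478	0.0293994
snp0000031	-0.00473271	0.029002
snp0000032	0.0210903	0.0422171
snp0000033	0.0161128	0.0350169
snp0000034	-0.0249764	0.0524404
snp0000035	0.206454	0.0323859
snp0000036	-0.0204599	0.029694
snp0000037	-0.372457	0.0283299
snp0000038	0.00412008	0.0304223
snp0000039	-0.0518774	0.0378021
snp0000040	-0.474022	0.0314334
snp0000041	-0.0373178	0.0333729
snp0000042	0.0240431	0.0322801
snp0000043	0.00220116	0.0283353
snp0000044	0.243829	0.0363549
snp0000045	0.0210693	0.0344414
snp0000046	-0.0249919	0.0287582
snp0000047	0.0428853	0.0367749
snp0000048	-0.0234684	0.030489
snp0000049	-0.0547565	0.0302984
snp0000050	-0.0259501	0.0282846
snp0000051	-0.0103934	0.0291576
snp0000052	-0.00508984	0.0288288
snp0000053	-0.0304026	0.0380359
snp0000054	-0.011423	0.0290812
snp0000055	0.0089368	0.0326488
snp0000056	0.00974354	0.0377449
snp0000057	0.00359245	0.0325367
snp0000058	0.207153	0.0328402
snp0000059	0.00909603	0.0427171
snp0000060	0.0543624	0.038738
snp0000061	-0.0255075	0.0315517
snp0000062	0.0990477	0.0515999
snp0000063	0.0245052	0.0283079
snp0000064	-0.262951	0.0427032
snp0000065	-0.0274527	0.0286974
snp0000066	0.536035	0.0339465
snp0000067	-8.61732e-05	0.0391056
snp0000068	-0.0398489	0.0436427
snp0000069	-0.019438	0.0299211
snp0000070	0.0108799	0.028912
snp0000071	0.00932726	0.0335517
snp0000072	-0.021592	0.0286093
snp0000073	-0.0155397	0.0328476
snp0000074	-0.0352167	0.0385324
snp0000075	-0.0747511	0.028714
snp0000076	-0.0217968	0.0367278
snp0000077	-0.0186415	0.0291738
snp0000078	-0.00583759	0.0551148
snp0000079	-0.0280851	0.0286497
snp0000080	-0.373617	0.0472937
snp0000081	-0.041757	0.0295648
snp0000082	0.0924397	0.0566766
snp0000083	-0.045281	0.0401432
snp0000084	0.0151107	0.0344637
snp0000085	0.0686141	0.0361003
snp0000086	-0.0198919	0.0283861
snp0000087	-0.0174731	0.0470035
snp0000088	-0.0243253	0.0358514
snp0000089	0.231819	0.0291429
snp0000090	0.0158779	0.0286977
snp0000091	-0.0431874	0.0283713
snp0000092	0.279472	0.0337451
snp0000093	-0.0753069	0.054151
snp0000094	0.0146924	0.033905
snp0000095	-0.238079	0.0311898
snp0000096	-0.267273	0.0303431
snp0000097	-0.0299645	0.0294072
snp0000098	-0.0937227	0.057122
snp0000099	0.0227385	0.0333063
snp0000100	-0.0218979	0.0291244
snp0000101	0.0290201	0.0405174
snp0000102	0.105864	0.0530648
snp0000103	-0.331307	0.0435309
snp0000104	-0.387287	0.049492
snp0000105	0.0323316	0.0283993
snp0000106	-0.0213045	0.0317626
snp0000107	0.0095853	0.0332471
snp0000108	0.0049302	0.0300915
snp0000109	0.0154658	0.0284452
snp0000110	0.000266117	0.0296979
snp0000111	0.0110787	0.0380136
snp0000112	0.0271199	0.0429045
snp0000113	-0.0602672	0.0283972
snp0000114	-0.0150282	0.0550251
snp0000115	0.0111266	0.0293369
snp0000116	0.380276	0.0290065
snp0000117	0.00409885	0.0315113
snp0000118	0.0543322	0.0314238
snp0000119	-0.00374998	0.028457
snp0000120	0.00334142	0.0370528
snp0000121	-0.00425532	0.0346931
snp0000122	0.0793862	0.0338103
snp0000123	0.184254	0.0346501
snp0000124	0.528431	0.0522848
snp0000125	0.0360913	0.0317158
snp0000126	-0.0209542	0.0282892
snp0000127	0.703374	0.0323637
snp0000128	0.222083	0.0283283
snp0000129	0.0329718	0.032729
snp0000130	-0.0528349	0.0301396
snp0000131	-0.227197	0.033004
snp0000132	-0.0113618	0.0293787
snp0000133	0.00772451	0.041012
snp0000134	-0.00262102	0.0423129
snp0000135	-0.00424645	0.0286172
snp0000136	0.0180168	0.0300729
snp0000137	0.03721	0.0407179
snp0000138	0.047508	0.0285059
snp0000139	0.0238639	0.0395334
snp0000140	-0.0364182	0.0313407
snp0000141	-0.0564566	0.0411422
snp0000142	0.0398537	0.0298744
snp0000143	-0.0111417	0.0283113
snp0000144	0.0106818	0.03021
snp0000145	0.463294	0.0292909
snp0000146	0.0202183	0.0303241
snp0000147	-0.0122644	0.0291842
snp0000148	-0.0205125	0.0625047
snp0000149	0.0258783	0.0590931
snp0000150	-0.0247033	0.0315076
snp0000151	-0.00789861	0.0348206
snp0000152	-0.370568	0.0295589
snp0000153	-0.0312528	0.0284606
snp0000154	0.00565738	0.0348463
snp0000155	0.0127806	0.0283622
snp0000156	-0.260972	0.0284072
snp0000157	0.0198988	0.0595672
snp0000158	0.285038	0.0283089
snp0000159	-0.0109409	0.0623634
snp0000160	-0.0509678	0.0324486
snp0000161	0.0603244	0.0497894
snp0000162	0.0414878	0.0284565
snp0000163	0.0431432	0.0498722
snp0000164	0.0171044	0.0289966
snp0000165	0.00239458	0.0289129
snp0000166	-0.0120859	0.029939
snp0000167	0.00573097	0.0295749
snp0000168	-0.0172382	0.0311641
snp0000169	0.313738	0.0283007
snp0000170	0.0118048	0.0296851
snp0000171	0.000306009	0.0305839
snp0000172	-0.00808003	0.0316197
snp0000173	0.0104008	0.0344626
snp0000174	0.0205086	0.0283431
snp0000175	0.0400734	0.028317
snp0000176	-0.0434088	0.0316073
snp0000177	-0.017297	0.02885
snp0000178	0.0598345	0.0349878
snp0000179	-0.00474957	0.0289718
snp0000180	0.0473873	0.0295321
snp0000181	-0.0227762	0.0285175
snp0000182	0.0748259	0.0633916
snp0000183	-0.0285933	0.0332639
snp0000184	-0.0497569	0.0572083
snp0000185	0.00883155	0.0298782
snp0000186	-0.231107	0.0311031
snp0000187	-0.031713	0.0285091
snp0000188	-0.0312916	0.0282897
snp0000189	0.0181386	0.0588861
snp0000190	-0.0378003	0.0348169
snp0000191	0.257267	0.0315739
snp0000192	0.05433	0.0419867
snp0000193	-0.0497398	0.0412119
snp0000194	-0.0584366	0.0333929
snp0000195	-0.0915068	0.0416844
snp0000196	0.0221289	0.0283671
snp0000197	-0.0431719	0.0397727
snp0000198	0.0293438	0.0288781
snp0000199	-0.00628825	0.0298862
snp0000200	-0.0383228	0.0286276
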