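snp	beta	se
snp0000001	0.0228682	0.0692092
snp0000002	-0.0158807	0.0390252
snp0000003	0.0497175	0.0325968
snp0000004	-0.0350679	0.0317879
snp0000005	0.0444504	0.033249
snp0000006	0.0352529	0.0637819
snp0000007	-0.0334158	0.031628
snp0000008	-0.253761	0.0321745
snp0000009	-0.030775	0.0338475
snp0000010	-0.0702774	0.0351226
snp0000011	0.0661998	0.0346783
snp0000012	0.057545	0.0366767
snp0000013	0.00446105	0.0317962
snp0000014	-0.0452261	0.0318368
snp0000015	0.0165892	0.0323335
snp0000016	-0.0337719	0.0342007
snp0000017	0.0211675	0.0354432
snp0000018	0.268751	0.0326356
snp0000019	0.00673099	0.0355652
snp0000020	0.596944	0.0338632
snp0000021	0.0371421	0.0345103
snp0000022	0.0349334	0.0326208
snp0000023	0.0209745	0.0497458
snp0000024	-0.00491732	0.0394808
snp0000025	0.0297782	0.0317738
snp0000026	0.00637218	0.0317626
snp0000027	0.0592687	0.0409264
snp0000028	-0.0406634	0.0317142
snp0000029	-0.00321388	0.0380097
snp0000030	0.0362095	0.0328695
snp0000031	-0.0223961	0.0324252
snp0000032	-0.0814398	0.0472001
snp0000033	0.0221545	0.0391501
snp0000034	0.272933	0.0586302
snp0000035	-0.0177185	0.0362085
snp0000036	-0.220472	0.0331989
snp0000037	-0.302066	0.0316738
snp0000038	0.00152314	0.0340132
snp0000039	0.0400342	0.042264
snp0000040	-0.284153	0.0351436
snp0000041	0.00337406	0.037312
snp0000042	-0.0627663	0.0360902
snp0000043	-0.0539282	0.0316799
snp0000044	0.353022	0.040646
snp0000045	0.0268841	0.0385067
snp0000046	0.0185227	0.0321526
snp0000047	-0.0219695	0.0411156
snp0000048	-0.0437	0.0340877
snp0000049	0.014553	0.0338746
snp0000050	-0.0357163	0.0316231
snp0000051	0.0788822	0.0325991
snp0000052	0.300842	0.0322316
snp0000053	0.0134476	0.0425255
snp0000054	-0.0513522	0.0325138
snp0000055	0.0189413	0.0365025
snp0000056	0.0479137	0.0422001
snp0000057	0.0113644	0.0363772
snp0000058	0.391968	0.0367165
snp0000059	0.0747646	0.0477591
snp0000060	0.0311328	0.0433104
snp0000061	0.0223764	0.0352759
snp0000062	0.0614926	0.0576904
snp0000063	0.0108205	0.0316492
snp0000064	0.150076	0.0477436
snp0000065	0.348284	0.0320847
snp0000066	0.0407366	0.0379533
snp0000067	0.0400679	0.0437214
snp0000068	0.0350174	0.0487941
snp0000069	0.0353089	0.0334528
snp0000070	0.0113327	0.0323246
snp0000071	-0.0726247	0.037512
snp0000072	-0.0256126	0.0319861
snp0000073	0.0860438	0.0367247
snp0000074	0.0827524	0.0430805
snp0000075	-0.00351654	0.0321032
snp0000076	-0.103184	0.0410629
snp0000077	-0.0247768	0.0326173
snp0000078	-0.0927669	0.0616202
snp0000079	-0.0537565	0.0320313
snp0000080	0.0502374	0.0528759
snp0000081	0.00413027	0.0330544
snp0000082	0.0911457	0.0633664
snp0000083	-0.0594837	0.0448815
snp0000084	-0.261696	0.0385316
snp0000085	0.0259204	0.0403614
snp0000086	0.0367051	0.0317367
snp0000087	-0.00912155	0.0525515
snp0000088	-0.0386629	0.0400831
snp0000089	0.0604019	0.0325828
snp0000090	0.0540429	0.032085
snp0000091	0.033538	0.0317201
snp0000092	0.279882	0.0377281
snp0000093	0.453264	0.0605427
snp0000094	-0.0769077	0.0379069
snp0000095	0.0740695	0.0348712
snp0000096	0.0101509	0.0339247
snp0000097	-0.0271129	0.0328783
snp0000098	0.0973513	0.0638643
snp0000099	-0.0228944	0.0372375
snp0000100	-0.0149707	0.032562
snp0000101	0.0200969	0.0452998
snp0000102	-0.0828211	0.0593282
snp0000103	-0.254179	0.0486691
snp0000104	-0.0586869	0.0553337
snp0000105	0.0372954	0.0317514
snp0000106	0.011732	0.0355116
snp0000107	-0.0107214	0.0371713
snp0000108	0.0444617	0.0336433
snp0000109	-0.0014462	0.0318027
snp0000110	-0.00713187	0.0332033
snp0000111	0.00572926	0.0425005
snp0000112	-0.0309397	0.0479687
snp0000113	0.00181198	0.031749
snp0000114	0.0572864	0.06152
snp0000115	0.00668009	0.0327997
snp0000116	0.323505	0.0324302
snp0000117	-0.0209044	0.0352307
snp0000118	-0.0108409	0.0351328
snp0000119	0.0425202	0.0318158
snp0000120	-0.299948	0.0414263
snp0000121	-0.0546479	0.0387881
snp0000122	0.02436	0.0378011
snp0000123	-0.0158395	0.03874
snp0000124	0.318246	0.0584562
snp0000125	-0.0328791	0.0354594
snp0000126	0.0250719	0.0316283
snp0000127	-0.0249341	0.0361837
snp0000128	-0.00131919	0.031672
snp0000129	0.450009	0.0365922
snp0000130	0.317958	0.0336971
snp0000131	-0.0245591	0.0368996
snp0000132	0.0147788	0.0328464
snp0000133	-0.0251292	0.0458528
snp0000134	0.0878466	0.0473073
snp0000135	0.0128645	0.031995
snp0000136	-0.0626926	0.0336225
snp0000137	-0.140686	0.045524
snp0000138	-0.00237766	0.0318706
snp0000139	0.0100684	0.0441997
snp0000140	0.0486585	0.03504
snp0000141	0.0186671	0.0459983
snp0000142	0.0855512	0.0334006
snp0000143	0.316158	0.031653
snp0000144	0.215261	0.0337758
snp0000145	0.475238	0.0327482
snp0000146	0.0268483	0.0339034
snp0000147	0.0271234	0.0326289
snp0000148	0.0383443	0.0698824
snp0000149	-0.0820747	0.0660681
snp0000150	-0.0145616	0.0352265
snp0000151	0.00276558	0.0389306
snp0000152	-0.234868	0.0330479
snp0000153	0.0102506	0.0318199
snp0000154	-0.0310284	0.0389594
snp0000155	0.0287646	0.0317099
snp0000156	-0.235071	0.0317602
snp0000157	-0.433514	0.0665981
snp0000158	0.259941	0.0316504
snp0000159	-0.0475379	0.0697244
snp0000160	0.0529617	0.0362787
snp0000161	-0.0480125	0.0556662
snp0000162	-0.0254645	0.0318153
snp0000163	-0.0382027	0.0557588
snp0000164	0.0590459	0.0324192
snp0000165	-0.00338592	0.0323256
snp0000166	-0.40256	0.0334728
snp0000167	-0.0339758	0.0330658
snp0000168	-0.0147776	0.0348426
snp0000169	-0.00503566	0.0316411
snp0000170	0.284526	0.0331889
snp0000171	-0.0103766	0.0341938
snp0000172	0.0246248	0.0353519
snp0000173	0.00434516	0.0385304
snp0000174	0.00571207	0.0316885
snp0000175	0.067156	0.0316594
snp0000176	-0.0239325	0.0353381
snp0000177	0.0314579	0.0322553
snp0000178	0.0429252	0.0391175
snp0000179	0.0540091	0.0323915
snp0000180	0.0107018	0.0330179
snp0000181	0.00799592	0.0318836
snp0000182	0.0108656	0.070874
snp0000183	0.0265995	0.0371902
snp0000184	0.0390507	0.0639608
snp0000185	-0.00941406	0.0334049
snp0000186	0.03081	0.0347743
snp0000187	0.0189373	0.0318742
snp0000188	0.022144	0.0316289
snp0000189	0.185325	0.0658367
snp0000190	0.0107857	0.0389264
snp0000191	-0.0181354	0.0353006
snp0000192	0.0198198	0.0469425
snp0000193	-0.0122362	0.0460763
snp0000194	-0.0287607	0.0373344
snp0000195	-0.0175467	0.0466046
snp0000196	0.00349576	0.0317153
snp0000197	0.0432471	0.0444672
snp0000198	0.0115261	0.0322866
snp0000199	-0.0275386	0.0334138
snp0000200	-0.00498122	0.0320067
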