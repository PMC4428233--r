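age	sex	qx
0	male	0.00422504926
1	male	0.00023728554
2	male	0.00024092133
3	male	0.00024491145
4	male	0.00024929044
5	male	0.00025409619
6	male	0.00025937030
7	male	0.00026515839
8	male	0.00027151056
9	male	0.00027848178
10	male	0.00028613237
11	male	0.00029452853
12	male	0.00030374292
13	male	0.00031385525
14	male	0.00032495304
15	male	0.00033713229
16	male	0.00035049839
17	male	0.00036516696
18	male	0.00038126491
19	male	0.00039893149
20	male	0.00041831953
21	male	0.00043959673
22	male	0.00046294712
23	male	0.00048857265
24	male	0.00051669494
25	male	0.00054755716
26	male	0.00058142617
27	male	0.00061859479
28	male	0.00065938434
29	male	0.00070414739
30	male	0.00075327082
31	male	0.00080717913
32	male	0.00086633808
33	male	0.00093125874
34	male	0.00100250182
35	male	0.00108068254
36	male	0.00116647583
37	male	0.00126062221
38	male	0.00136393405
39	male	0.00147730253
40	male	0.00160170530
41	male	0.00173821473
42	male	0.00188800713
43	male	0.00205237269
44	male	0.00223272645
45	male	0.00243062028
46	male	0.00264775601
47	male	0.00288599978
48	male	0.00314739769
49	male	0.00343419303
50	male	0.00374884498
51	male	0.00409404911
52	male	0.00447275976
53	male	0.00488821447
54	male	0.00534396057
55	male	0.00584388424
56	male	0.00639224216
57	male	0.00699369588
58	male	0.00765334930
59	male	0.00837678935
60	male	0.00917013013
61	male	0.01004006078
62	male	0.01099389735
63	male	0.01203963875
64	male	0.01318602735
65	male	0.01444261401
66	male	0.01581982823
67	male	0.01732905324
68	male	0.01898270636
69	male	0.02079432472
70	male	0.02277865635
71	male	0.02495175653
72	male	0.02733108937
73	male	0.02993563416
74	male	0.03278599613
75	male	0.03590452077
76	male	0.03931541090
77	male	0.04304484497
78	male	0.04712109505
79	male	0.05157464226
80	male	0.05643828680
81	male	0.06174724929
82	male	0.06753925903
83	male	0.07385462424
84	male	0.08073627789
85	male	0.08822979186
86	male	0.09638335065
87	male	0.10524767445
88	male	0.11487587956
89	male	0.12532326274
90	male	0.13664699382
91	male	0.14890569940
92	male	0.16215891860
93	male	0.17646641010
94	male	0.19188728891
95	male	0.20847897044
96	male	0.22629589995
97	male	0.24538804728
98	male	0.26579914987
99	male	0.28756469310
0	female	0.00421210410
1	female	0.00022302182
2	female	0.00022526749
3	female	0.00022773202
4	female	0.00023043674
5	female	0.00023340505
6	female	0.00023666266
7	female	0.00024023774
8	female	0.00024416124
9	female	0.00024846712
10	female	0.00025319263
11	female	0.00025837868
12	female	0.00026407013
13	female	0.00027031625
14	female	0.00027717108
15	female	0.00028469393
16	female	0.00029294992
17	female	0.00030201046
18	female	0.00031195397
19	female	0.00032286648
20	female	0.00033484240
21	female	0.00034798535
22	female	0.00036240904
23	female	0.00037823824
24	female	0.00039560990
25	female	0.00041467428
26	female	0.00043559629
27	female	0.00045855689
28	female	0.00048375467
29	female	0.00051140753
30	female	0.00054175461
31	female	0.00057505831
32	female	0.00061160657
33	female	0.00065171534
34	female	0.00069573134
35	female	0.00074403497
36	female	0.00079704368
37	female	0.00085521547
38	female	0.00091905289
39	female	0.00098910731
40	female	0.00106598371
41	female	0.00115034581
42	female	0.00124292178
43	female	0.00134451050
44	female	0.00145598833
45	female	0.00157831667
46	female	0.00171255008
47	female	0.00185984535
48	female	0.00202147126
49	female	0.00219881939
50	female	0.00239341590
51	female	0.00260693444
52	female	0.00284121028
53	female	0.00309825571
54	female	0.00338027697
55	female	0.00368969269
56	female	0.00402915405
57	female	0.00440156677
58	female	0.00481011522
59	female	0.00525828856
60	female	0.00574990935
61	female	0.00628916472
62	female	0.00688064024
63	female	0.00752935680
64	female	0.00824081070
65	female	0.00902101716
66	female	0.00987655748
67	female	0.01081463018
68	female	0.01184310619
69	female	0.01297058856
70	female	0.01420647674
71	female	0.01556103573
72	female	0.01704547027
73	female	0.01867200426
74	female	0.02045396550
75	female	0.02240587576
76	female	0.02454354627
77	female	0.02688417832
78	female	0.02944646878
79	female	0.03225072010
80	female	0.03531895408
81	female	0.03867502851
82	female	0.04234475536
83	female	0.04635601897
84	female	0.05073889215
85	female	0.05552574740
86	female	0.06075136011
87	female	0.06645299959
88	female	0.07267050292
89	female	0.07944632576
90	female	0.08682556284
91	female	0.09485592973
92	female	0.10358769586
93	female	0.11307355727
94	female	0.12336843584
95	female	0.13452918971
96	female	0.14661421807
97	female	0.15968294157
98	female	0.17379513789
99	female	0.18901011093
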