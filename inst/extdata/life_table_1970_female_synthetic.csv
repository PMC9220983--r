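"age","hazard"
0,0.000426
1,0.00042879197
2,0.00043188375
3,0.00043530754
4,0.00043909899
5,0.00044329757
6,0.00044794701
7,0.00045309573
8,0.00045879734
9,0.0004651112
10,0.00047210306
11,0.00047984574
12,0.00048841985
13,0.00049791468
14,0.0005084291
15,0.0005200726
16,0.00053296641
17,0.0005472448
18,0.00056305646
19,0.00058056603
20,0.00059995584
21,0.00062142779
22,0.00064520548
23,0.00067153649
24,0.00070069502
25,0.0007329847
26,0.00076874175
27,0.00080833852
28,0.00085218733
29,0.00090074477
30,0.00095451649
31,0.0010140624
32,0.0010800025
33,0.0011530236
34,0.0012338859
35,0.0013234314
36,0.0014225927
37,0.0015324022
38,0.0016540035
39,0.0017886628
40,0.0019377822
41,0.0021029146
42,0.0022857795
43,0.002488281
44,0.0027125279
45,0.0029608552
46,0.0032358487
47,0.003540372
48,0.003877596
49,0.0042510324
50,0.0046645696
51,0.0051225139
52,0.0056296338
53,0.00619121
54,0.0068130903
55,0.0075017502
56,0.0082643608
57,0.0091088631
58,0.010044051
59,0.011079663
60,0.012226482
61,0.013496451
62,0.014902793
63,0.016460153
64,0.018184748
65,0.020094536
66,0.022209404
67,0.024551374
68,0.027144832
69,0.030016785
70,0.033197138
71,0.036719009
72,0.04061907
73,0.044937933
74,0.049720571
75,0.055016785
76,0.060881725
77,0.067376463
78,0.074568628
79,0.082533113
80,0.091352852
81,0.10111968
82,0.11193531
83,0.12391236
84,0.13717555
85,0.15186298
86,0.1681276
87,0.18613878
88,0.20608405
89,0.22817112
90,0.25262997
91,0.2797153
92,0.30970915
93,0.34292384
94,0.37970524
95,0.42043635
96,0.46554131
97,0.5154898
98,0.57080193
99,0.63205367
100,0.69988284
101,0.77499573
102,0.85817451
103,0.95028532
104,1.0522873
105,1.1652426
106,1.2903275
107,1.4288443
108,1.5822357
109,50
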