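"age","qx"
0,0.000417
1,0.000419
2,0.000421
3,0.000423
4,0.000425
5,0.000428
6,0.000431
7,0.000434
8,0.000438
9,0.000441
10,0.000446
11,0.00045
12,0.000456
13,0.000461
14,0.000468
15,0.000474
16,0.000482
17,0.000491
18,5e-04
19,0.00051
20,0.000521
21,0.000534
22,0.000548
23,0.000563
24,0.000579
25,0.000598
26,0.000618
27,0.000641
28,0.000665
29,0.000692
30,0.000722
31,0.000756
32,0.000792
33,0.000832
34,0.000877
35,0.000926
36,0.000979
37,0.001039
38,0.001105
39,0.001177
40,0.001257
41,0.001344
42,0.001441
43,0.001548
44,0.001666
45,0.001796
46,0.001939
47,0.002097
48,0.002272
49,0.002464
50,0.002675
51,0.002909
52,0.003166
53,0.00345
54,0.003763
55,0.004109
56,0.004489
57,0.004909
58,0.005372
59,0.005882
60,0.006445
61,0.007065
62,0.007749
63,0.008503
64,0.009335
65,0.010252
66,0.011263
67,0.012378
68,0.013607
69,0.014963
70,0.016457
71,0.018105
72,0.019922
73,0.021926
74,0.024135
75,0.026571
76,0.029257
77,0.032219
78,0.035484
79,0.039085
80,0.043055
81,0.047433
82,0.05226
83,0.057583
84,0.063452
85,0.069923
86,0.077058
87,0.084926
88,0.093601
89,0.103166
90,0.113713
91,0.125343
92,0.138166
93,0.152305
94,0.167895
95,0.185085
96,0.20404
97,0.22494
98,0.247985
99,0.273395
100,0.301413
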