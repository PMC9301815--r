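age,q_annual
35,0.0013634279
36,0.0014056349
37,0.0014527359
38,0.0015052979
39,0.0015639539
40,0.0016294099
41,0.0017024537
42,0.0017839643
43,0.0018749222
44,0.0019764215
45,0.0020896825
46,0.0022160666
47,0.0023570924
48,0.0025144537
49,0.0026900395
50,0.0028859568
51,0.0031045551
52,0.0033484541
53,0.003620575
54,0.0039241743
55,0.0042628818
56,0.0046407433
57,0.0050622676
58,0.0055324778
59,0.0060569701
60,0.0066419768
61,0.0072944379
62,0.0080220783
63,0.0088334954
64,0.0097382532
65,0.010746988
66,0.011871522
67,0.013124994
68,0.01452199
69,0.016078704
70,0.017813093
71,0.019745061
72,0.021896651
73,0.02429225
74,0.026958812
75,0.02992609
76,0.033226891
77,0.036897324
78,0.040977077
79,0.045509679
80,0.050542774
81,0.056128378
82,0.062323122
83,0.069188463
84,0.076790852
85,0.085201826
86,0.094498027
87,0.10476109
88,0.11607738
89,0.12853755
90,0.14223583
91,0.15726903
92,0.1737352
93,0.19173185
94,0.21135369
95,0.23268975
96,0.25581997
97,0.28081099
98,0.30771135
99,0.33654587
100,1
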