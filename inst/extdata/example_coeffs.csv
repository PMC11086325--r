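j,value_waves
1,0.080853999999999995
2,0.12657299999999999
3,-0.56469800000000003
4,3.6128749999999998
5,0.36312800000000001
6,0.30276399999999998
7,-0.014199
8,0.22672800000000001
9,-0.015918999999999999
10,0.18293200000000001
11,0.10439
12,-0.0050169999999999998
13,-0.022303
14,-0.111109
15,-0.01137
16,0.025437999999999999
17,-0.0053330000000000001
18,-0.10625800000000001
19,0.052804999999999998
20,-0.097618999999999997
21,-0.0051450000000000003
22,-0.0086090000000000003
23,0.037904
24,0.024292999999999999
25,-0.0034380000000000001
26,-0.035625999999999998
27,-0.0061330000000000004
28,0.0050499999999999998
29,-0.0060889999999999998
30,0.010351000000000001
31,0.0070479999999999996
32,0.004555
33,-0.0064000000000000003
34,0.0046010000000000001
35,-0.017631999999999998
36,-0.0036340000000000001
37,0.0037910000000000001
38,-0.001805
39,0.0010300000000000001
40,0.00018100000000000001
41,-0.012071
42,-0.0042550000000000001
43,-0.0039220000000000001
44,-0.0085850000000000006
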