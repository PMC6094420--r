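sample,set,nominal_1e7M,predicted_1e7M,rep_pct
1,calibration,11,11.13,1.20
2,calibration,12,11.57,-3.58
3,calibration,13,12.95,-0.39
4,calibration,1.5,1.51,0.46
5,calibration,16,16.41,2.58
6,calibration,17,17.10,0.61
7,calibration,18,17.78,-1.22
8,calibration,19,19.29,1.52
9,validation,21,20.79,-1.00
10,calibration,22,21.74,-1.17
11,calibration,23,22.99,-0.04
12,calibration,24,23.72,-1.17
13,calibration,25,25.27,1.06
14,calibration,2.5,2.55,1.91
15,validation,26,26.03,0.12
16,calibration,27,27.06,0.24
17,calibration,28,27.50,-1.79
18,test,29,28.68,-1.09
19,calibration,31,30.92,-0.25
20,validation,32,30.78,-3.81
21,calibration,33,33.18,0.55
22,validation,34,34.12,0.35
23,calibration,35,35.25,0.73
24,validation,3.5,3.59,2.59
25,test,36,36.72,1.99
26,calibration,37,37.00,0.01
27,calibration,38,38.05,0.14
28,validation,39,40.43,3.66
29,calibration,41,41.08,0.20
30,calibration,42,42.17,0.41
31,calibration,43,43.15,0.35
32,test,44,44.73,1.66
33,calibration,45,44.60,-0.89
34,calibration,4.5,4.52,0.42
35,validation,46,46.80,1.74
36,calibration,47,47.35,0.74
37,test,5.5,5.68,3.31
38,calibration,7.5,7.68,2.35
39,validation,8.5,8.15,-4.07
40,calibration,9.5,9.76,2.77
41,calibration,10,9.79,-2.13
42,test,1,1.04,3.82
43,calibration,0.1,0.10,3.87
44,calibration,20,20.22,1.11
45,validation,2,2.00,0.13
46,calibration,0.2,0.20,0.10
47,test,30,30.78,2.61
48,test,3,3.01,0.24
49,calibration,0.3,0.30,0.59
50,test,40,39.17,-2.07
51,test,4,4.01,0.14
52,calibration,0.4,0.39,-2.58
53,calibration,5,5.03,0.66
54,calibration,0.5,0.49,-1.34
55,test,6,6.08,1.38
56,calibration,7,6.86,-2.00
57,calibration,0.7,0.69,-2.02
58,calibration,8,7.90,-1.23
59,calibration,0.8,0.80,-0.54
60,test,9,8.74,-2.91
61,test,0.9,0.90,0.15
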