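pc,eigenvalue,variance_pct
1,4626.63,39.79
2,2350.70,20.21
3,957.80,8.24
4,801.76,6.89
5,583.61,5.02
6,500.02,4.30
7,324.43,2.79
8,286.83,2.47
9,221.43,1.90
10,172.67,1.48
11,131.93,1.13
12,87.53,0.75
13,70.92,0.61
14,63.22,0.54
15,46.45,0.40
16,42.52,0.37
17,40.21,0.35
18,28.25,0.24
19,26.95,0.23
20,22.54,0.19
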