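run,alpha,beta,gamma,R1,R2,R3
1,10,0.2,1,2.73,1.70,17.95
2,10,0.2,2,2.73,2.03,22.18
3,10,0.2,3,2.73,2.80,26.30
4,10,0.5,1,2.78,1.90,18.58
5,10,0.5,2,2.78,2.03,21.50
6,10,0.5,3,2.78,2.80,24.20
7,10,1.0,1,2.83,2.08,26.35
8,10,1.0,2,2.83,2.13,29.68
9,10,1.0,3,2.83,2.85,32.70
10,14,0.2,1,2.53,1.63,15.35
11,14,0.2,2,2.53,2.03,19.63
12,14,0.2,3,2.53,2.55,24.13
13,14,0.5,1,2.55,1.80,17.05
14,14,0.5,2,2.55,2.03,20.15
15,14,0.5,3,2.55,2.58,23.15
16,14,1.0,1,2.60,1.98,24.43
17,14,1.0,2,2.60,2.03,27.98
18,14,1.0,3,2.60,2.63,31.40
19,20,0.2,1,2.33,1.58,12.90
20,20,0.2,2,2.33,2.03,17.00
21,20,0.2,3,2.33,2.40,21.68
22,20,0.5,1,2.40,1.75,15.45
23,20,0.5,2,2.40,2.03,18.68
24,20,0.5,3,2.40,2.43,21.95
25,20,1.0,1,2.43,1.90,22.53
26,20,1.0,2,2.43,2.03,26.25
27,20,1.0,3,2.43,2.45,29.98
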