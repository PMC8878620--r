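primer_code,total_alleles,polymorphic_alleles,pct_polymorphism,PIC,MI,Rp
1CM0102,4,3,75,0.47,0.35,2.14
2CM0304,3,2,67,0.55,0.37,0.7
3CM0506,5,5,100,0.69,0.69,3.12
4CM0910,5,4,80,0.58,0.47,2.16
5CM1112,3,1,33,0.33,0.11,0.01
6CM1314,3,2,67,0.42,0.28,0.63
7CM1516,2,1,50,0.5,0.25,0.02
8CM1718,2,1,50,0.49,0.25,0.03
10CM2122,3,2,67,0.66,0.44,0.05
12CM2728,3,2,67,0.58,0.39,0.51
13CM2930,5,3,60,0.57,0.34,0.31
14CM3132,3,3,100,0.5,0.5,2.84
15CM3334,5,4,80,0.65,0.52,1.47
17CM3738,3,2,67,0.16,0.11,0.95
18CM3940,4,3,75,0.65,0.48,0.84
20CM4344,4,3,75,0.67,0.5,0.63
21CM038,5,3,60,0.39,0.23,1.31
22CM075,3,2,67,0.54,0.36,0.74
25CM003,2,1,50,0.29,0.14,0.85
30CM056,3,3,100,0.52,0.52,1.26
31CM154,4,3,75,0.41,0.31,2.36
33CM163,2,1,50,0.49,0.25,0.04
34CM014,3,3,100,0.34,0.34,1.62
35CM007,4,3,75,0.4,0.3,1.32
36CM126,3,2,67,0.41,0.27,0.67
38CM168,2,1,50,0.49,0.25,0.03
39CM125,2,1,50,0.49,0.24,0.05
42CM128,2,1,50,0.47,0.24,0.11
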