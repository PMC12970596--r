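step,left,right,height
1,-3,-4,0
2,-26,1,0
3,-8,-11,0
4,-31,-36,1.92296e-16
5,-15,-19,2.71948e-16
6,-35,4,2.71948e-16
7,-22,-23,3.84593e-16
8,-32,-33,3.84593e-16
9,-13,-21,4.00297e-16
10,-12,5,5.20741e-16
11,-30,9,5.20741e-16
12,-28,6,5.76889e-16
13,-16,-17,6.84387e-16
14,-25,11,7.02167e-16
15,-24,10,8.15844e-16
16,8,12,8.15844e-16
17,7,15,9.28879e-16
18,-34,13,9.74217e-16
19,-2,-29,1.28518e-15
20,-1,14,1.32298e-15
21,17,20,1.74838e-15
22,16,18,1.81412e-15
23,19,21,2.49244e-15
24,-20,23,2.65295e-15
25,-10,24,6.0024e-15
26,-6,22,1.20765e-14
27,-5,26,2.19706e-14
28,-18,2,2.00329
29,-7,3,2.00329
30,-27,28,2.44949
31,-9,27,2.55497
32,25,29,3.53553
33,-14,31,3.67423
34,30,32,3.93346
35,33,34,5.47723
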