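energy_kev,water,iodine
35,0.3155,26.50
40,0.2683,22.10
50,0.2269,12.32
60,0.2059,7.579
70,0.1950,5.107
80,0.1837,3.510
90,0.1766,2.700
100,0.1707,2.100
110,0.1659,1.700
120,0.1614,1.380
130,0.1575,1.160
140,0.1538,0.992
150,0.1505,0.862
160,0.1475,0.760
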