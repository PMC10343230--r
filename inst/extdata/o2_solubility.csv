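temp_C,o2_ppm
0,14.60
5,12.73
10,11.26
15,10.07
20,9.07
25,8.21
30,7.53
35,6.92
40,6.38
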