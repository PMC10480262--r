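r_cm	g
0.10	0.9896
0.15	0.9925
0.20	0.9944
0.25	0.9957
0.35	0.9974
0.50	0.9987
0.75	0.9997
1.00	1.0000
1.25	0.9998
1.50	0.9994
2.00	0.9976
2.50	0.9947
3.00	0.9906
4.00	0.9793
5.00	0.9640
6.00	0.9447
8.00	0.8966
10.00	0.8388
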