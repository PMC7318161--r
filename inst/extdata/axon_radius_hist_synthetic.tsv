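radius_um	count
0.15	31
0.2022	144
0.2724	427
0.3672	814
0.4948	1000
0.6669	791
0.8988	403
1.2113	132
1.6324	28
2.2	4
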