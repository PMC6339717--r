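# time_unit=hour
# label=MTX (LbL-LNP)
time,dissolution_percent,error
1,2,1
2,5,1
4,10,1
5,15,1
7.5,19,1
10,21,1
12,25,1
24,35,1
35,40,1
48,45,1
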