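# time_unit=hour
# label=DOX (LbL-LNP)
time,dissolution_percent,error
1,10,7
2,20,7
4,30,3
5,38,3
7.5,42,7
10,48,2
12,50,8
24,60,2
35,65,5
48,70,1
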