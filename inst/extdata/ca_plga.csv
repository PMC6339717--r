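# time_unit=day
# label=SMV (CA-PLGA NPs)
time,dissolution_percent,error
1,20,2.5
2,27,2.5
3,32,3
4,38,2.5
5,43,5
7,49,3
8,53,5
12,55,3
15,57,3
18,58,2.5
24,58,3
30,59,3
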