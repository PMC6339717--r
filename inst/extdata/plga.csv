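# time_unit=day
# label=SMV (PLGA NPs)
time,dissolution_percent,error
1,10,2.5
2,18,2.5
3,23,4
4,27,3
5,29,3
7,34,3
8,36,3
12,40,3
15,43,3
18,44,4
24,45,3
30,46,2.5
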