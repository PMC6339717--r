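# time_unit=hour
# label=PD-PCL-NC
time,dissolution_percent,error
0,0,1
0.5,45,1
1,65,1
2,80,1
3,90,1
4,95,1
5,97.5,1
6,100,2.5
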