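depth,duration,events,total
0,0,7,95
1,0,13,90
0,1,15,96
1,1,14,83
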