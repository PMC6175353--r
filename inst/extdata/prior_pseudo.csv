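subgroup,dose,proportion,weight
0,100,0.16666666666666666,2
0,260,0.5,1
1,100,0.16666666666666666,2
1,260,0.5,1
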