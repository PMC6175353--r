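dose,subgroup,dlt_weight,no_dlt_weight,is_pseudo
100,0,0,5,FALSE
150,0,0,4,FALSE
180,0,0,4,FALSE
215,0,0,6,FALSE
245,0,2,5,FALSE
260,0,1,0,FALSE
100,1,1,5,FALSE
150,1,0,4,FALSE
180,1,0,8,FALSE
215,1,2,2,FALSE
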