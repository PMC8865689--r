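sample_id,stressor,level,duration_min,stock_id,dilution_exponent,volume_ml,plaques
heat_55_5,heat,55,5,stock_A,6,0.1,31
heat_55_5,heat,55,5,stock_A,6,0.1,28
heat_55_5,heat,55,5,stock_A,6,0.1,35
heat_70_90,heat,70,90,stock_A,4,0.1,22
heat_70_90,heat,70,90,stock_A,4,0.1,17
heat_70_90,heat,70,90,stock_A,4,0.1,25
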