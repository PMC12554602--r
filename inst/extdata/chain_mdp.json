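{"states":["s1","s2","s3","s4"],"actions":["advance","stay"],"gamma":0.90000000000000002,"terminal":"s4","initDist":[0.33333333333333331,0.33333333333333331,0.33333333333333331,0],"trans":[0,0,0,0,1,0,0,0,1,0,0,0,0,1,0,0,0,1,0,0,0,0,1,0,0,0,1,1,0,0,0,1],"reward":[0,0,0,0,0.5,0,0,0,0,0,0,0,0,0.5,0,0,0,0,0,0,0,0,0.5,0,0,0,10,0,0,0,0,0]}
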