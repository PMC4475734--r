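condition,class,tau_rec_ms,tau_dep_ms,p0,x0,h
control,STD,32,5,0.35,1,0.1
6-OHDA,STD,33,6,0.35,1,0.1
control,STF,15,60,0.2,1,0.05
6-OHDA,STF,10,1000,0.3,4,0.07
control,STB,13,170,0.29,0.7,0.3
6-OHDA,STB,9.5,200,0.54,0.7,0.3
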