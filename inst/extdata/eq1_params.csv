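condition,class,A,tau_rec_ms,tau_dep_ms,B,C
control,STD,1.15,107.7,17.2,-0.5,0.92
6-OHDA,STD,1.41,120.2,39.3,-0.23,0.35
control,STF,2.57,53.6,29.3,2.4,-4.4
6-OHDA,STF,3.09,158.2,37.7,4.7,-18
control,STB,4.4,62,96,3.2,-13.2
6-OHDA,STB,1.9,70,161,0.41,-2
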