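condition,class,a_max_pa,k,i_h_tu
control,STD,159,2.3,2
6-OHDA,STD,180,2.5,2.9
control,STF,89,1.2,3.1
6-OHDA,STF,139,1,4.9
control,STB,135,0.73,4.5
6-OHDA,STB,214,1.05,4.6
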