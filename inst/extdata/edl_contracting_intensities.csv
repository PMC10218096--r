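family_h,family_k,intensity,error,phase
1,0,100.00,NA,+
1,1,68.75,3.72,+
2,0,20.49,5.27,-
2,1,12.96,1.00,-
3,0,2.51,2.25,+
2,2,3.78,0.38,+
3,1,0.60,9.75,-
4,0,1.36,3.72,-
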