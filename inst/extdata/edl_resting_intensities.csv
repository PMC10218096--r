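family_h,family_k,intensity,error,phase
1,0,100.00,NA,+
1,1,36.34,3.49,+
2,0,15.72,1.43,-
2,1,6.24,1.07,-
3,0,6.73,1.13,+
2,2,0.31,0.23,+
3,1,2.36,0.46,-
4,0,1.24,0.27,-
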