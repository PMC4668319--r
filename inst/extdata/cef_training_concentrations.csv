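sample,CEF,7-ACA,5-MER
s1,18,0.13,0.065
s2,18,0.15,0.07
s3,20,0.15,0.09
s4,20,0.2,0.07
s5,26,0.15,0.065
s6,20,0.13,0.085
s7,18,0.18,0.085
s8,24,0.18,0.07
s9,24,0.15,0.085
s10,20,0.18,0.065
s11,24,0.13,0.09
s12,18,0.2,0.09
s13,26,0.2,0.085
s14,26,0.18,0.09
s15,24,0.2,0.065
s16,26,0.13,0.07
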