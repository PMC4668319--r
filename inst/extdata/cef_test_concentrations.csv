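sample,CEF,7-ACA,5-MER
s1,25,0.17,0.09
s2,19,0.14,0.07
s3,22,0.18,0.075
s4,21,0.14,0.08
s5,23,0.15,0.065
s6,25,0.2,0.085
s7,19,0.13,0.08
s8,22,0.16,0.07
s9,21,0.16,0.08
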