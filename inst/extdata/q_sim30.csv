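item,A1,A2,A3,A4,A5
I1,1,0,0,0,0
I2,0,1,0,0,0
I3,0,0,1,0,0
I4,0,0,0,1,0
I5,0,0,0,0,1
I6,1,0,0,0,0
I7,0,1,0,0,0
I8,0,0,1,0,0
I9,0,0,0,1,0
I10,0,0,0,0,1
I11,1,1,0,0,0
I12,1,0,1,0,0
I13,1,0,0,1,0
I14,1,0,0,0,1
I15,0,1,1,0,0
I16,0,1,0,1,0
I17,0,1,0,0,1
I18,0,0,1,1,0
I19,0,0,1,0,1
I20,0,0,0,1,1
I21,1,1,1,0,0
I22,1,1,0,1,0
I23,1,1,0,0,1
I24,1,0,1,1,0
I25,1,0,1,0,1
I26,1,0,0,1,1
I27,0,1,1,1,0
I28,0,1,1,0,1
I29,0,1,0,1,1
I30,0,0,1,1,1
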