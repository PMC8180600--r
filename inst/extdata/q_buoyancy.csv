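item,A1,A2,A3,A4,A5,A6,A7
I1,1,0,0,0,0,0,0
I2,0,1,0,0,0,0,0
I3,0,0,1,0,0,0,0
I4,0,0,0,1,0,0,0
I5,0,0,1,0,0,0,1
I6,0,0,1,0,0,0,1
I7,1,1,0,0,1,0,0
I8,1,1,0,0,1,0,0
I9,0,0,1,1,0,0,0
I10,0,0,1,1,0,1,0
I11,1,1,1,0,1,0,1
I12,0,0,1,1,0,1,1
I13,1,1,1,1,0,1,0
I14,1,1,1,1,1,1,1
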