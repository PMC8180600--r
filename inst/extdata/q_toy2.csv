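item,A1,A2
Item1,1,1
Item2,0,1
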