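{"attributes":["A1","A2","A3","A4","A5","A6","A7"],"edges":[["A1","A2"],["A2","A5"],["A3","A4"],["A4","A6"],["A3","A7"],["A6","A7"]]}
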