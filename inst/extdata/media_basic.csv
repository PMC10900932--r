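medium,element,fraction,density
bone,H,0.035,1.9
bone,C,0.16,1.9
bone,N,0.042,1.9
bone,O,0.445,1.9
bone,Na,0.003,1.9
bone,Mg,0.002,1.9
bone,P,0.095,1.9
bone,S,0.003,1.9
bone,Ca,0.215,1.9
marrow,H,0.105,0.98
marrow,C,0.414,0.98
marrow,N,0.034,0.98
marrow,O,0.439,0.98
marrow,Na,0.001,0.98
marrow,Mg,0.002,0.98
marrow,P,0.002,0.98
marrow,S,0.002,0.98
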