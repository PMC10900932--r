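medium,element,fraction,density
bone,H,0.012,1.9
bone,C,0.0287,1.9
bone,O,0.44,1.9
bone,F,0.0096,1.9
bone,Na,0.007,1.9
bone,Mg,0.011,1.9
bone,Si,0.000007,1.9
bone,P,0.16,1.9
bone,Cl,0.0074,1.9
bone,K,0.0007,1.9
bone,Ca,0.331,1.9
bone,Fe,0.0000067,1.9
bone,Zn,0.00017,1.9
marrow,H,0.116,0.98
marrow,O,0.899,0.98
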