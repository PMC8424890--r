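feature,Any,BB,SC,P,H,A,D,C,R
A,1,1,1,1,0,0,1,0,0
D,1,1,1,1,0,1,0,0,0
H,1,1,1,0,1,0,0,0,0
N,1,0,1,0,0,0,0,1,0
P,1,0,1,0,0,0,0,1,1
R,1,1,1,0,1,0,0,0,1
vdW,1,1,1,0,0,0,0,0,0
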