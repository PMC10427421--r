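,MEL,BCC,AKIEC,BKL,NV,DF,VASC
MEL,4,-1,-1,-6,-6,-6,-6
BCC,0,3,0,-4,-4,-4,-4
AKIEC,0,0,3,-3,-3,-3,-3
BKL,-1,-1,-1,1,0,0,0
NV,-1,-1,-1,0,1,0,0
DF,-1,-1,-1,0,0,1,0
VASC,-1,-1,-1,0,0,0,1
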