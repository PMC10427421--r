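,DISMISS,MONITOR,EXCISE
MEL,-6,-2,4
BCC,-4,-1,3
AKIEC,-3,0,2
BKL,1,0.5,-2
NV,1,0.5,-2
DF,1,0.5,-2
VASC,1,0.5,-2
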