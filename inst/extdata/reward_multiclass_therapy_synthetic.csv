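,DISMISS,TREAT_LOCALLY,EXCISE
MEL,-6,-4,4
BCC,-4,1,3
AKIEC,-3,3,1
BKL,1,-1,-2
NV,1,-1,-2
DF,1,-1,-2
VASC,1,-1,-2
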