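channel,row,col
C5,0,0
Fz,0,2
C6,0,4
FC3,1,0
FC1,1,1
FCz,1,2
FC2,1,3
FC4,1,4
C3,2,0
C1,2,1
Cz,2,2
C2,2,3
C4,2,4
CP3,3,0
CP1,3,1
CPz,3,2
CP2,3,3
CP4,3,4
P1,4,1
Pz,4,2
P2,4,3
POz,4,4
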