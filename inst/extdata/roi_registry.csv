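node,lobe,index
STG,temporal,1
LAT,temporal,2
MED,temporal,3
aSTG,temporal,4
aMTG,temporal,5
aITG,temporal,6
aFG,temporal,7
aPhG,temporal,8
HG,temporal,9
mSTG,temporal,10
mMTG,temporal,11
mITG,temporal,12
mFG,temporal,13
mPhG,temporal,14
pSTG,temporal,15
pMTG,temporal,16
pITG,temporal,17
pFG,temporal,18
LG1,temporal,19
LG2,temporal,20
DLPFC,frontal,21
BA44,frontal,22
BA45,frontal,23
BA47,frontal,24
medOFC,frontal,25
latOFC,frontal,26
5Ci,parietal,27
5M,parietal,28
5L,parietal,29
7PC,parietal,30
7A,parietal,31
7P,parietal,32
7M,parietal,33
IPS1,parietal,34
IPS2,parietal,35
IPS3,parietal,36
PFop,parietal,37
PFt,parietal,38
PF,parietal,39
PFm,parietal,40
PFcm,parietal,41
PGa,parietal,42
PGp,parietal,43
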