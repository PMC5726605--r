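node,module,degree,closeness,betweenness,clustering
STG,2,6,2.62,3.47,0.73
LAT,2,7,2.52,11.95,0.52
MED,2,8,2.40,40.25,0.46
aSTG,2,6,2.67,15.76,0.40
aMTG,2,6,2.52,13.27,0.40
aITG,3,7,2.21,36.83,0.38
aFG,3,8,2.64,19.96,0.50
aPhG,3,7,2.36,32.73,0.48
HG,4,3,2.83,1.12,0.67
mSTG,4,5,2.69,6.98,0.50
mMTG,4,9,2.10,84.50,0.28
mITG,3,6,2.36,19.74,0.60
mFG,3,9,2.36,28.50,0.53
mPhG,3,8,2.40,26.84,0.57
pSTG,4,7,2.36,17.89,0.62
pMTG,1,15,1.88,53.39,0.58
pITG,3,7,2.02,86.64,0.38
pFG,3,7,2.50,14.40,0.62
LG1,3,5,3.05,0.20,0.90
LG2,3,6,2.57,8.88,0.67
DLPFC,1,16,1.81,116.68,0.54
BA44,1,12,1.90,45.73,0.61
BA45,1,6,2.33,6.42,0.67
BA47,2,10,2.07,88.56,0.40
medOFC,2,6,2.24,23.80,0.60
latOFC,2,6,2.48,16.38,0.60
5Ci,5,4,2.67,0.00,1.00
5M,5,6,2.45,4.08,0.80
5L,5,8,2.57,2.28,0.71
7PC,5,20,1.76,160.73,0.45
7A,5,11,2.33,19.40,0.58
7P,5,7,2.43,5.35,0.76
7M,5,7,2.21,83.30,0.43
IPS1,1,15,2.10,18.97,0.64
IPS2,1,14,2.12,8.98,0.73
IPS3,5,13,2.14,13.94,0.65
PFop,1,10,2.19,3.78,0.87
PFt,1,10,2.21,0.53,0.91
PF,1,14,2.10,12.59,0.69
PFm,1,9,2.24,0.10,0.97
PFcm,1,15,1.93,35.78,0.62
PGa,1,11,2.19,4.39,0.82
PGp,5,8,2.45,1.92,0.82
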