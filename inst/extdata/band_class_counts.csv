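marker,primer,mb,ub,nb,pic_published
ISSR,ISSR1,4,4,1,0.46
ISSR,ISSR2,5,3,1,0.36
ISSR,ISSR3,6,0,1,0.08
ISSR,ISSR4,3,0,1,0.14
ISSR,ISSR5,4,4,3,0.47
ISSR,ISSR6,2,0,3,0.33
ISSR,ISSR7,1,2,0,0.59
ISSR,ISSR8,3,2,2,0.41
ISSR,ISSR9,2,3,1,0.54
ISSR,ISSR10,1,6,2,0.72
SCoT,SCoT1,6,0,3,0.19
SCoT,SCoT2,2,11,0,0.75
SCoT,SCoT3,3,2,2,0.41
SCoT,SCoT4,3,1,1,0.29
SCoT,SCoT5,5,7,8,0.53
SCoT,SCoT6,1,8,5,0.71
SCoT,SCoT7,0,12,7,0.77
SCoT,SCoT8,3,10,4,0.66
SCoT,SCoT9,4,3,5,0.45
SCoT,SCoT10,5,2,5,0.41
SCoT,SCoT11,2,3,5,0.54
PROTEIN,SDS-PAGE,5,2,0,NA
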