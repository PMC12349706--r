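interval_pair,genotype,plant,A,B,C,D,E,F,G,H,I,J,K,L,n
I1bc,WT,1,326,63,66,1,1,2,1,1,2,0,0,0,463
I1bc,WT,2,326,63,66,0,0,2,1,1,2,0,0,0,461
I1bc,WT,3,326,63,66,0,0,2,1,1,1,0,0,0,460
I1bc,WT,4,325,63,66,0,0,1,1,1,1,0,0,0,458
I1bc,WT,5,325,63,66,0,0,1,1,1,1,0,0,0,458
I1bc,srs2-1,1,318,63,66,1,1,2,1,1,2,0,0,0,455
I1bc,srs2-1,2,317,63,66,0,0,1,1,1,1,0,0,0,450
I1bc,srs2-1,3,317,63,66,0,0,1,1,1,1,0,0,0,450
I1bc,srs2-1,4,317,63,66,0,0,1,0,0,1,0,0,0,448
I1bc,srs2-1,5,317,62,66,0,0,1,0,0,1,0,0,0,447
I1bc,srs2-3,1,297,59,62,1,0,2,1,1,2,0,0,0,425
I1bc,srs2-3,2,296,59,62,0,0,1,1,1,1,0,0,0,421
I1bc,srs2-3,3,296,58,62,0,0,1,1,1,1,0,0,0,420
I1bc,srs2-3,4,296,58,61,0,0,1,0,0,1,0,0,0,417
I1bc,srs2-3,5,296,58,61,0,0,1,0,0,1,0,0,0,417
I2fg,WT,1,1220,56,59,0,0,1,0,0,1,0,0,0,1337
I2fg,WT,2,1219,56,58,0,0,0,0,0,1,0,0,0,1334
I2fg,WT,3,1219,56,58,0,0,0,0,0,0,0,0,0,1333
I2fg,WT,4,1219,55,58,0,0,0,0,0,0,0,0,0,1332
I2fg,WT,5,1219,55,58,0,0,0,0,0,0,0,0,0,1332
I2fg,WT,6,1219,55,58,0,0,0,0,0,0,0,0,0,1332
I2fg,srs2-1,1,1189,55,57,0,0,1,0,0,0,0,0,0,1302
I2fg,srs2-1,2,1189,55,57,0,0,0,0,0,0,0,0,0,1301
I2fg,srs2-1,3,1188,55,57,0,0,0,0,0,0,0,0,0,1300
I2fg,srs2-1,4,1188,54,57,0,0,0,0,0,0,0,0,0,1299
I2fg,srs2-1,5,1188,54,57,0,0,0,0,0,0,0,0,0,1299
I2fg,srs2-1,6,1188,54,57,0,0,0,0,0,0,0,0,0,1299
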