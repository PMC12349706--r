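genotype,cell_id,ring,ring3,rod,univalent_pairs
WT,1,4,0,1,0
WT,2,4,0,1,0
WT,3,4,0,1,0
WT,4,4,0,1,0
WT,5,4,0,1,0
WT,6,4,0,1,0
WT,7,4,0,1,0
WT,8,4,0,1,0
WT,9,4,0,1,0
WT,10,4,0,1,0
WT,11,4,0,1,0
WT,12,4,0,1,0
WT,13,4,0,1,0
WT,14,4,0,1,0
WT,15,4,0,1,0
WT,16,4,0,1,0
WT,17,4,0,1,0
WT,18,4,0,1,0
WT,19,4,0,1,0
WT,20,4,0,1,0
WT,21,3,0,2,0
WT,22,3,0,2,0
WT,23,3,0,2,0
WT,24,3,0,2,0
WT,25,3,0,2,0
WT,26,3,0,2,0
WT,27,3,0,2,0
WT,28,3,0,2,0
WT,29,3,0,2,0
WT,30,3,0,2,0
WT,31,3,0,2,0
WT,32,3,0,2,0
WT,33,3,0,2,0
WT,34,3,0,2,0
WT,35,3,0,2,0
WT,36,3,0,2,0
WT,37,3,0,2,0
WT,38,3,0,2,0
WT,39,3,0,2,0
WT,40,3,0,2,0
WT,41,5,0,0,0
WT,42,5,0,0,0
WT,43,5,0,0,0
WT,44,5,0,0,0
WT,45,5,0,0,0
WT,46,5,0,0,0
WT,47,5,0,0,0
WT,48,5,0,0,0
WT,49,5,0,0,0
WT,50,5,0,0,0
srs2-1,1,5,0,0,0
srs2-1,2,5,0,0,0
srs2-1,3,5,0,0,0
srs2-1,4,5,0,0,0
srs2-1,5,5,0,0,0
srs2-1,6,5,0,0,0
srs2-1,7,5,0,0,0
srs2-1,8,5,0,0,0
srs2-1,9,5,0,0,0
srs2-1,10,5,0,0,0
srs2-1,11,5,0,0,0
srs2-1,12,5,0,0,0
srs2-1,13,5,0,0,0
srs2-1,14,5,0,0,0
srs2-1,15,5,0,0,0
srs2-1,16,4,0,1,0
srs2-1,17,4,0,1,0
srs2-1,18,4,0,1,0
srs2-1,19,4,0,1,0
srs2-1,20,4,0,1,0
srs2-1,21,4,0,1,0
srs2-1,22,4,0,1,0
srs2-1,23,4,0,1,0
srs2-1,24,4,0,1,0
srs2-1,25,4,0,1,0
srs2-1,26,4,0,1,0
srs2-1,27,4,0,1,0
srs2-1,28,4,0,1,0
srs2-1,29,4,0,1,0
srs2-1,30,4,0,1,0
srs2-1,31,4,0,1,0
srs2-1,32,4,0,1,0
srs2-1,33,4,0,1,0
srs2-1,34,4,0,1,0
srs2-1,35,4,0,1,0
srs2-1,36,4,0,1,0
srs2-1,37,4,0,1,0
srs2-1,38,4,0,1,0
srs2-1,39,4,0,1,0
srs2-1,40,4,0,1,0
srs2-1,41,4,0,1,0
srs2-1,42,4,0,1,0
srs2-1,43,4,0,1,0
srs2-1,44,4,0,1,0
srs2-1,45,4,0,1,0
srs2-1,46,3,0,2,0
srs2-1,47,3,0,2,0
srs2-1,48,3,0,2,0
srs2-1,49,3,0,2,0
srs2-1,50,3,0,2,0
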