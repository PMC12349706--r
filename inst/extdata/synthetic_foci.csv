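kind,genotype,treatment,cell_id,count
MLH1-HEI10,WT,none,1,7
MLH1-HEI10,WT,none,2,7
MLH1-HEI10,WT,none,3,7
MLH1-HEI10,WT,none,4,7
MLH1-HEI10,WT,none,5,7
MLH1-HEI10,WT,none,6,7
MLH1-HEI10,WT,none,7,8
MLH1-HEI10,WT,none,8,8
MLH1-HEI10,WT,none,9,8
MLH1-HEI10,WT,none,10,8
MLH1-HEI10,WT,none,11,8
MLH1-HEI10,WT,none,12,8
MLH1-HEI10,WT,none,13,8
MLH1-HEI10,WT,none,14,8
MLH1-HEI10,WT,none,15,8
MLH1-HEI10,WT,none,16,8
MLH1-HEI10,WT,none,17,8
MLH1-HEI10,WT,none,18,8
MLH1-HEI10,WT,none,19,9
MLH1-HEI10,WT,none,20,9
MLH1-HEI10,WT,none,21,9
MLH1-HEI10,WT,none,22,9
MLH1-HEI10,WT,none,23,9
MLH1-HEI10,WT,none,24,9
MLH1-HEI10,WT,none,25,10
MLH1-HEI10,WT,none,26,10
MLH1-HEI10,WT,none,27,10
MLH1-HEI10,WT,none,28,10
MLH1-HEI10,WT,none,29,10
MLH1-HEI10,WT,none,30,10
MLH1-HEI10,srs2-1,none,1,7
MLH1-HEI10,srs2-1,none,2,7
MLH1-HEI10,srs2-1,none,3,7
MLH1-HEI10,srs2-1,none,4,8
MLH1-HEI10,srs2-1,none,5,8
MLH1-HEI10,srs2-1,none,6,8
MLH1-HEI10,srs2-1,none,7,8
MLH1-HEI10,srs2-1,none,8,8
MLH1-HEI10,srs2-1,none,9,8
MLH1-HEI10,srs2-1,none,10,8
MLH1-HEI10,srs2-1,none,11,9
MLH1-HEI10,srs2-1,none,12,9
MLH1-HEI10,srs2-1,none,13,9
MLH1-HEI10,srs2-1,none,14,9
MLH1-HEI10,srs2-1,none,15,9
MLH1-HEI10,srs2-1,none,16,9
MLH1-HEI10,srs2-1,none,17,9
MLH1-HEI10,srs2-1,none,18,9
MLH1-HEI10,srs2-1,none,19,9
MLH1-HEI10,srs2-1,none,20,9
MLH1-HEI10,srs2-1,none,21,10
MLH1-HEI10,srs2-1,none,22,10
MLH1-HEI10,srs2-1,none,23,10
MLH1-HEI10,srs2-1,none,24,10
MLH1-HEI10,srs2-1,none,25,10
MLH1-HEI10,srs2-1,none,26,10
MLH1-HEI10,srs2-1,none,27,10
MLH1-HEI10,srs2-1,none,28,10
MLH1-HEI10,srs2-1,none,29,10
MLH1-HEI10,srs2-1,none,30,10
MLH1-HEI10,srs2-1,none,31,11
MLH1-HEI10,srs2-1,none,32,11
MLH1-HEI10,srs2-1,none,33,11
MLH1-HEI10,srs2-1,none,34,11
MLH1-HEI10,srs2-1,none,35,11
MLH1,WT,none,1,9
MLH1,WT,none,2,9
MLH1,WT,none,3,9
MLH1,WT,none,4,9
MLH1,WT,none,5,10
MLH1,WT,none,6,10
MLH1,WT,none,7,10
MLH1,WT,none,8,10
MLH1,WT,none,9,10
MLH1,WT,none,10,10
MLH1,WT,none,11,10
MLH1,WT,none,12,10
MLH1,WT,none,13,11
MLH1,WT,none,14,11
MLH1,WT,none,15,11
MLH1,WT,none,16,11
MLH1,WT,none,17,11
MLH1,WT,none,18,11
MLH1,WT,none,19,11
MLH1,WT,none,20,11
MLH1,WT,none,21,11
MLH1,WT,none,22,11
MLH1,WT,none,23,11
MLH1,WT,none,24,11
MLH1,WT,none,25,12
MLH1,WT,none,26,12
MLH1,WT,none,27,12
MLH1,WT,none,28,12
MLH1,WT,none,29,12
MLH1,WT,none,30,12
MLH1,WT,none,31,12
MLH1,WT,none,32,12
MLH1,WT,none,33,12
MLH1,WT,none,34,12
MLH1,WT,none,35,12
MLH1,WT,none,36,12
MLH1,WT,none,37,12
MLH1,WT,none,38,12
MLH1,WT,none,39,12
MLH1,WT,none,40,12
MLH1,WT,none,41,13
MLH1,WT,none,42,13
MLH1,WT,none,43,13
MLH1,WT,none,44,13
MLH1,WT,none,45,13
MLH1,WT,none,46,13
MLH1,WT,none,47,13
MLH1,WT,none,48,13
MLH1,WT,none,49,13
MLH1,WT,none,50,13
MLH1,srs2-1,none,1,10
MLH1,srs2-1,none,2,10
MLH1,srs2-1,none,3,10
MLH1,srs2-1,none,4,10
MLH1,srs2-1,none,5,10
MLH1,srs2-1,none,6,10
MLH1,srs2-1,none,7,10
MLH1,srs2-1,none,8,11
MLH1,srs2-1,none,9,11
MLH1,srs2-1,none,10,11
MLH1,srs2-1,none,11,11
MLH1,srs2-1,none,12,11
MLH1,srs2-1,none,13,11
MLH1,srs2-1,none,14,11
MLH1,srs2-1,none,15,11
MLH1,srs2-1,none,16,11
MLH1,srs2-1,none,17,11
MLH1,srs2-1,none,18,12
MLH1,srs2-1,none,19,12
MLH1,srs2-1,none,20,12
MLH1,srs2-1,none,21,12
MLH1,srs2-1,none,22,12
MLH1,srs2-1,none,23,12
MLH1,srs2-1,none,24,12
MLH1,srs2-1,none,25,12
MLH1,srs2-1,none,26,12
MLH1,srs2-1,none,27,12
MLH1,srs2-1,none,28,12
MLH1,srs2-1,none,29,12
MLH1,srs2-1,none,30,13
MLH1,srs2-1,none,31,13
MLH1,srs2-1,none,32,13
MLH1,srs2-1,none,33,13
MLH1,srs2-1,none,34,13
MLH1,srs2-1,none,35,13
MLH1,srs2-1,none,36,13
MLH1,srs2-1,none,37,13
MLH1,srs2-1,none,38,13
MLH1,srs2-1,none,39,13
MLH1,srs2-1,none,40,13
MLH1,srs2-1,none,41,13
MLH1,srs2-1,none,42,13
MLH1,srs2-1,none,43,13
MLH1,srs2-1,none,44,13
MLH1,srs2-1,none,45,13
MLH1,srs2-1,none,46,13
MLH1,srs2-1,none,47,14
MLH1,srs2-1,none,48,14
MLH1,srs2-1,none,49,14
MLH1,srs2-1,none,50,14
MLH1,srs2-1,none,51,14
MLH1,srs2-1,none,52,14
MLH1,srs2-1,none,53,14
MLH1,srs2-1,none,54,14
MLH1,srs2-1,none,55,14
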