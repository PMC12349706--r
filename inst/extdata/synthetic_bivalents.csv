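genotype,cell_id,ring,ring3,rod,univalent_pairs
zip4,1,0,0,0,5
zip4,2,0,0,0,5
zip4,3,0,0,0,5
zip4,4,0,0,0,5
zip4,5,0,0,0,5
zip4,6,0,0,0,5
zip4,7,0,0,0,5
zip4,8,0,0,0,5
zip4,9,0,0,0,5
zip4,10,0,0,0,5
zip4,11,0,0,1,4
zip4,12,0,0,1,4
zip4,13,0,0,1,4
zip4,14,0,0,1,4
zip4,15,0,0,1,4
zip4,16,0,0,1,4
zip4,17,0,0,1,4
zip4,18,0,0,1,4
zip4,19,0,0,1,4
zip4,20,0,0,1,4
zip4,21,0,0,1,4
zip4,22,0,0,1,4
zip4,23,0,0,1,4
zip4,24,0,0,1,4
zip4,25,0,0,1,4
zip4,26,0,0,1,4
zip4,27,0,0,1,4
zip4,28,0,0,1,4
zip4,29,0,0,1,4
zip4,30,0,0,1,4
zip4,31,0,0,1,4
zip4,32,0,0,1,4
zip4,33,0,0,1,4
zip4,34,0,0,1,4
zip4,35,0,0,1,4
zip4,36,0,0,2,3
zip4,37,0,0,2,3
zip4,38,0,0,2,3
zip4,39,0,0,2,3
zip4,40,0,0,2,3
zip4,41,0,0,2,3
zip4,42,0,0,2,3
zip4,43,0,0,2,3
zip4,44,0,0,2,3
zip4,45,0,0,2,3
zip4,46,0,0,2,3
zip4,47,0,0,2,3
zip4,48,0,0,2,3
zip4,49,0,0,2,3
zip4,50,0,0,2,3
zip4,51,0,0,3,2
zip4,52,0,0,3,2
zip4,53,0,0,3,2
zip4,54,0,0,3,2
zip4,55,0,0,3,2
zip4,56,0,0,5,0
zip4 srs2-1,1,0,0,0,5
zip4 srs2-1,2,0,0,0,5
zip4 srs2-1,3,0,0,0,5
zip4 srs2-1,4,0,0,0,5
zip4 srs2-1,5,0,0,0,5
zip4 srs2-1,6,0,0,0,5
zip4 srs2-1,7,0,0,0,5
zip4 srs2-1,8,0,0,0,5
zip4 srs2-1,9,0,0,0,5
zip4 srs2-1,10,0,0,0,5
zip4 srs2-1,11,0,0,1,4
zip4 srs2-1,12,0,0,1,4
zip4 srs2-1,13,0,0,1,4
zip4 srs2-1,14,0,0,1,4
zip4 srs2-1,15,0,0,1,4
zip4 srs2-1,16,0,0,1,4
zip4 srs2-1,17,0,0,1,4
zip4 srs2-1,18,0,0,1,4
zip4 srs2-1,19,0,0,1,4
zip4 srs2-1,20,0,0,1,4
zip4 srs2-1,21,0,0,1,4
zip4 srs2-1,22,0,0,1,4
zip4 srs2-1,23,0,0,1,4
zip4 srs2-1,24,0,0,1,4
zip4 srs2-1,25,0,0,1,4
zip4 srs2-1,26,0,0,1,4
zip4 srs2-1,27,0,0,1,4
zip4 srs2-1,28,0,0,1,4
zip4 srs2-1,29,0,0,1,4
zip4 srs2-1,30,0,0,1,4
zip4 srs2-1,31,0,0,1,4
zip4 srs2-1,32,0,0,1,4
zip4 srs2-1,33,0,0,2,3
zip4 srs2-1,34,0,0,2,3
zip4 srs2-1,35,0,0,2,3
zip4 srs2-1,36,0,0,2,3
zip4 srs2-1,37,0,0,2,3
zip4 srs2-1,38,0,0,2,3
zip4 srs2-1,39,0,0,2,3
zip4 srs2-1,40,0,0,2,3
zip4 srs2-1,41,0,0,3,2
zip4 srs2-1,42,0,0,3,2
msh5 srs2-1,1,0,0,0,5
msh5 srs2-1,2,0,0,0,5
msh5 srs2-1,3,0,0,0,5
msh5 srs2-1,4,0,0,0,5
msh5 srs2-1,5,0,0,0,5
msh5 srs2-1,6,0,0,0,5
msh5 srs2-1,7,0,0,0,5
msh5 srs2-1,8,0,0,0,5
msh5 srs2-1,9,0,0,0,5
msh5 srs2-1,10,0,0,0,5
msh5 srs2-1,11,0,0,0,5
msh5 srs2-1,12,0,0,0,5
msh5 srs2-1,13,0,0,0,5
msh5 srs2-1,14,0,0,0,5
msh5 srs2-1,15,0,0,0,5
msh5 srs2-1,16,0,0,0,5
msh5 srs2-1,17,0,0,0,5
msh5 srs2-1,18,0,0,0,5
msh5 srs2-1,19,0,0,0,5
msh5 srs2-1,20,0,0,0,5
msh5 srs2-1,21,0,0,1,4
msh5 srs2-1,22,0,0,1,4
msh5 srs2-1,23,0,0,1,4
msh5 srs2-1,24,0,0,1,4
msh5 srs2-1,25,0,0,1,4
msh5 srs2-1,26,0,0,1,4
msh5 srs2-1,27,0,0,1,4
msh5 srs2-1,28,0,0,1,4
msh5 srs2-1,29,0,0,1,4
msh5 srs2-1,30,0,0,1,4
msh5 srs2-1,31,0,0,1,4
msh5 srs2-1,32,0,0,1,4
msh5 srs2-1,33,0,0,1,4
msh5 srs2-1,34,0,0,1,4
msh5 srs2-1,35,0,0,1,4
msh5 srs2-1,36,0,0,1,4
msh5 srs2-1,37,0,0,1,4
msh5 srs2-1,38,0,0,1,4
msh5 srs2-1,39,0,0,1,4
msh5 srs2-1,40,0,0,1,4
msh5 srs2-1,41,0,0,1,4
msh5 srs2-1,42,0,0,1,4
msh5 srs2-1,43,0,0,1,4
msh5 srs2-1,44,0,0,1,4
msh5 srs2-1,45,0,0,1,4
msh5 srs2-1,46,0,0,1,4
msh5 srs2-1,47,0,0,1,4
msh5 srs2-1,48,0,0,1,4
msh5 srs2-1,49,0,0,1,4
msh5 srs2-1,50,0,0,1,4
msh5 srs2-1,51,0,0,2,3
msh5 srs2-1,52,0,0,2,3
msh5 srs2-1,53,0,0,2,3
msh5 srs2-1,54,0,0,2,3
msh5 srs2-1,55,0,0,2,3
msh5 srs2-1,56,0,0,2,3
msh5 srs2-1,57,0,0,2,3
msh5 srs2-1,58,0,0,2,3
msh5 srs2-1,59,0,0,2,3
msh5 srs2-1,60,0,0,2,3
msh5 srs2-1,61,0,0,2,3
msh5 srs2-1,62,0,0,2,3
msh5 srs2-1,63,0,0,2,3
msh5 srs2-1,64,0,0,3,2
msh5 srs2-1,65,0,0,3,2
msh5 srs2-1,66,0,0,3,2
msh5 srs2-1,67,0,0,3,2
msh5 srs2-1,68,0,0,3,2
zip4 mus81,1,0,0,0,5
zip4 mus81,2,0,0,0,5
zip4 mus81,3,0,0,0,5
zip4 mus81,4,0,0,0,5
zip4 mus81,5,0,0,0,5
zip4 mus81,6,0,0,0,5
zip4 mus81,7,0,0,0,5
zip4 mus81,8,0,0,0,5
zip4 mus81,9,0,0,0,5
zip4 mus81,10,0,0,0,5
zip4 mus81,11,0,0,0,5
zip4 mus81,12,0,0,0,5
zip4 mus81,13,0,0,0,5
zip4 mus81,14,0,0,0,5
zip4 mus81,15,0,0,0,5
zip4 mus81,16,0,0,0,5
zip4 mus81,17,0,0,0,5
zip4 mus81,18,0,0,0,5
zip4 mus81,19,0,0,0,5
zip4 mus81,20,0,0,0,5
zip4 mus81,21,0,0,0,5
zip4 mus81,22,0,0,0,5
zip4 mus81,23,0,0,0,5
zip4 mus81,24,0,0,0,5
zip4 mus81,25,0,0,0,5
zip4 mus81,26,0,0,0,5
zip4 mus81,27,0,0,0,5
zip4 mus81,28,0,0,0,5
zip4 mus81,29,0,0,0,5
zip4 mus81,30,0,0,0,5
zip4 mus81,31,0,0,1,4
zip4 mus81,32,0,0,1,4
zip4 mus81,33,0,0,1,4
zip4 mus81,34,0,0,1,4
zip4 mus81,35,0,0,1,4
zip4 mus81,36,0,0,1,4
zip4 mus81,37,0,0,1,4
zip4 mus81,38,0,0,1,4
zip4 mus81,39,0,0,1,4
zip4 mus81,40,0,0,1,4
zip4 mus81,41,0,0,1,4
zip4 mus81,42,0,0,1,4
zip4 mus81,43,0,0,1,4
zip4 mus81,44,0,0,1,4
zip4 mus81,45,0,0,1,4
zip4 mus81,46,0,0,1,4
zip4 mus81,47,0,0,1,4
zip4 mus81,48,0,0,1,4
zip4 mus81,49,0,0,1,4
zip4 mus81,50,0,0,1,4
zip4 mus81,51,0,0,1,4
zip4 mus81,52,0,0,1,4
zip4 mus81,53,0,0,1,4
zip4 mus81,54,0,0,1,4
zip4 mus81,55,0,0,1,4
zip4 mus81,56,0,0,1,4
zip4 mus81,57,0,0,1,4
zip4 mus81,58,0,0,1,4
zip4 mus81,59,0,0,1,4
zip4 mus81,60,0,0,1,4
zip4 mus81,61,0,0,1,4
zip4 mus81,62,0,0,1,4
zip4 mus81,63,0,0,1,4
zip4 mus81,64,0,0,1,4
zip4 mus81,65,0,0,1,4
zip4 mus81,66,0,0,2,3
zip4 mus81,67,0,0,2,3
zip4 mus81,68,0,0,2,3
zip4 mus81,69,0,0,2,3
zip4 mus81,70,0,0,2,3
zip4 mus81,71,0,0,2,3
zip4 mus81,72,0,0,2,3
zip4 mus81,73,0,0,2,3
zip4 mus81,74,0,0,2,3
zip4 mus81,75,0,0,4,1
zip4 mus81,76,0,0,4,1
zip4 mus81,77,0,0,4,1
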