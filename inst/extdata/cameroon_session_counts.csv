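session_id,instrument,n_reported,n_pass,n_fail
S01,FACSCount,8,3,5
S01,CyFlow,3,2,1
S01,PIMA,2,1,1
S01,Other,1,1,0
S02,FACSCount,16,9,7
S02,CyFlow,13,5,8
S02,PIMA,17,11,6
S02,Other,4,4,0
S03,FACSCount,16,11,5
S03,CyFlow,11,6,5
S03,PIMA,19,16,3
S03,Other,2,2,0
S04,FACSCount,11,10,1
S04,CyFlow,14,12,2
S04,PIMA,32,31,1
S04,Other,2,2,0
S05,FACSCount,9,8,1
S05,CyFlow,13,10,3
S05,PIMA,33,28,5
S05,Other,2,2,0
S06,FACSCount,11,11,0
S06,CyFlow,8,7,1
S06,PIMA,33,30,3
S06,Other,2,2,0
S07,FACSCount,6,6,0
S07,CyFlow,2,2,0
S07,PIMA,9,8,1
S07,Other,1,0,1
S08,FACSCount,9,5,4
S08,CyFlow,5,4,1
S08,PIMA,15,13,2
S08,Other,2,1,1
S09,FACSCount,5,5,0
S09,CyFlow,9,7,2
S09,PIMA,32,29,3
S09,Other,2,2,0
S10,FACSCount,6,4,2
S10,CyFlow,7,2,5
S10,PIMA,32,29,3
S10,Other,2,1,1
S11,FACSCount,6,6,0
S11,CyFlow,8,5,3
S11,PIMA,37,36,1
S11,Other,3,2,1
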