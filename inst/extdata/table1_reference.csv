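compliance,peep,arm,state,p_peak,p_plat,peep_total,dp,costa,final_vt,final_rr,provenance,note
60,5,CTRL,baseline,16,11,5,6,44,400,20,reference_table,
60,5,MIRUS,baseline,16,12,6,6,45,400,20,reference_table,
60,5,ANA-100,baseline,16,12,6,6,45,400,20,reference_table,
60,5,ANA-50,baseline,16,12,6,6,45,400,20,reference_table,
60,15,CTRL,baseline,26,21,15,6,44,400,20,reference_table,
60,15,MIRUS,baseline,26,22,16,6,45,400,20,reference_table,
60,15,ANA-100,baseline,27,23,16,6,45,400,20,reference_table,
60,15,ANA-50,baseline,27,23,17,6,45,400,20,reference_table,
60,5,CTRL,vt_corrected,16,11,5,6,44,400,20,reference_table,
60,5,MIRUS,vt_corrected,18,15,6,9,55,560,20,reference_table,off_titration_grid
60,5,ANA-100,vt_corrected,19,16,6,9,57,580,20,reference_table,
60,5,ANA-50,vt_corrected,19,15,6,8,53,520,20,reference_table,
60,15,CTRL,vt_corrected,26,21,15,6,44,400,20,reference_table,
60,15,MIRUS,vt_corrected,29,25,16,8,54,580,20,reference_table,
60,15,ANA-100,vt_corrected,30,26,17,9,57,580,20,reference_table,
60,15,ANA-50,vt_corrected,29,25,17,8,53,520,20,reference_table,
60,5,CTRL,rr_corrected,16,11,5,6,44,400,20,reference_table,
60,5,MIRUS,rr_corrected,19,15,8,7,61,400,32,reference_table,
60,5,ANA-100,rr_corrected,20,16,8,8,67,400,35,reference_table,
60,5,ANA-50,rr_corrected,19,14,7,7,57,400,29,reference_table,
60,15,CTRL,rr_corrected,26,21,15,6,44,400,20,reference_table,
60,15,MIRUS,rr_corrected,30,26,19,7,65,400,35,reference_table,
60,15,ANA-100,rr_corrected,30,26,19,7,67,400,35,reference_table,
60,15,ANA-50,rr_corrected,28,24,17,7,57,400,26,reference_table,
40,5,CTRL,baseline,18,14,5,9,55,400,20,reference_table,
40,5,MIRUS,baseline,18,15,6,9,56,400,20,reference_table,
40,5,ANA-100,baseline,19,15,6,9,56,400,20,reference_table,
40,5,ANA-50,baseline,19,15,6,9,57,400,20,reference_table,
40,15,CTRL,baseline,29,24,15,9,55,400,20,reference_table,
40,15,MIRUS,baseline,29,25,16,9,56,400,20,reference_table,
40,15,ANA-100,baseline,29,25,16,9,56,400,20,reference_table,
40,15,ANA-50,baseline,29,25,16,9,57,400,20,reference_table,
40,5,CTRL,vt_corrected,18,14,5,9,55,400,20,reference_table,
40,5,MIRUS,vt_corrected,22,19,6,13,71,580,20,reference_table,
40,5,ANA-100,vt_corrected,23,20,6,14,74,580,20,reference_table,
40,5,ANA-50,vt_corrected,22,18,6,12,68,520,20,reference_table,
40,15,CTRL,vt_corrected,29,24,15,9,55,400,20,reference_table,
40,15,MIRUS,vt_corrected,32,28,16,12,71,580,20,reference_table,
40,15,ANA-100,vt_corrected,33,30,17,13,74,580,20,reference_table,
40,15,ANA-50,vt_corrected,32,28,16,12,68,520,20,reference_table,
40,5,CTRL,rr_corrected,18,14,5,9,55,400,20,reference_table,
40,5,MIRUS,rr_corrected,21,18,8,10,75,400,35,reference_table,
40,5,ANA-100,rr_corrected,21,17,7,10,76,400,35,reference_table,
40,5,ANA-50,rr_corrected,20,17,7,10,68,400,29,reference_table,
40,15,CTRL,rr_corrected,29,24,15,9,55,400,20,reference_table,
40,15,MIRUS,rr_corrected,32,28,18,10,75,400,35,reference_table,
40,15,ANA-100,rr_corrected,32,28,18,10,76,400,35,reference_table,
40,15,ANA-50,rr_corrected,31,27,17,10,68,400,29,reference_table,
20,5,CTRL,baseline,26,22,5,17,88,400,20,reference_table,
20,5,MIRUS,baseline,25,23,5,17,88,400,20,reference_table,
20,5,ANA-100,baseline,26,23,6,17,90,400,20,reference_table,
20,5,ANA-50,baseline,26,23,6,17,90,400,20,reference_table,
20,15,CTRL,baseline,36,32,15,17,88,400,20,reference_table,
20,15,MIRUS,baseline,36,33,16,17,88,400,20,reference_table,
20,15,ANA-100,baseline,37,34,16,17,90,400,20,reference_table,
20,15,ANA-50,baseline,37,34,16,17,90,400,20,reference_table,
20,5,CTRL,vt_corrected,26,22,5,17,88,400,20,reference_table,
20,5,MIRUS,vt_corrected,31,28,5,22,109,580,20,reference_table,
20,5,ANA-100,vt_corrected,34,32,6,25,123,580,20,reference_table,
20,5,ANA-50,vt_corrected,32,29,6,23,114,520,20,reference_table,
20,15,CTRL,vt_corrected,36,32,15,17,88,400,20,reference_table,
20,15,MIRUS,vt_corrected,41,38,16,22,109,580,20,reference_table,
20,15,ANA-100,vt_corrected,43,41,16,24,123,580,20,reference_table,
20,15,ANA-50,vt_corrected,41,38,16,22,114,520,20,reference_table,
20,5,CTRL,rr_corrected,26,22,5,17,88,400,20,reference_table,
20,5,MIRUS,rr_corrected,27,24,6,17,106,400,35,reference_table,
20,5,ANA-100,rr_corrected,27,24,6,18,107,400,35,reference_table,
20,5,ANA-50,rr_corrected,27,24,6,18,102,400,29,reference_table,
20,15,CTRL,rr_corrected,36,32,15,17,88,400,20,reference_table,
20,15,MIRUS,rr_corrected,37,34,17,18,106,400,35,reference_table,
20,15,ANA-100,rr_corrected,38,35,17,18,107,400,35,reference_table,
20,15,ANA-50,rr_corrected,37,34,16,18,102,400,26,reference_table,
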