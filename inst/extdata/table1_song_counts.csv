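pair,group,night,FR,NR,CC,CR,MB,sum,rep_sum,excluded,reason
MS_01,A,1,11,3,9,10,0,33,NA,FALSE,NA
MS_01,A,2,6,16,22,135,0,179,NA,FALSE,NA
MS_01,A,3,7,9,23,41,0,80,NA,FALSE,NA
MS_02,A,1,3,12,6,5,0,26,NA,FALSE,NA
MS_02,A,2,2,7,24,80,0,113,NA,FALSE,NA
MS_02,A,3,NA,NA,NA,NA,NA,NA,NA,TRUE,opened contact window in night 3
MS_03,A,1,5,3,0,3,0,11,7,FALSE,NA
MS_03,A,2,0,1,1,12,0,14,39,FALSE,NA
MS_03,A,3,0,0,0,12,0,12,21,FALSE,NA
MS_04,A,1,3,2,17,4,0,26,22,FALSE,NA
MS_04,A,2,6,2,3,16,0,27,39,FALSE,NA
MS_04,A,3,1,1,20,9,0,31,25,FALSE,NA
MS_05,A,1,5,6,7,6,0,24,19,FALSE,NA
MS_05,A,2,7,24,35,298,0,364,413,FALSE,NA
MS_05,A,3,13,10,24,179,0,226,166,FALSE,NA
MS_06,A,1,7,3,33,5,0,48,48,FALSE,NA
MS_06,A,2,5,18,14,93,0,130,173,FALSE,NA
MS_06,A,3,1,6,5,44,0,56,73,FALSE,NA
MS_07,B,1,5,3,11,5,0,24,NA,FALSE,NA
MS_07,B,2,7,5,20,85,0,117,NA,FALSE,NA
MS_07,B,3,0,0,15,13,0,28,NA,FALSE,NA
MS_07,B,4,0,2,23,6,1,31,NA,FALSE,NA
MS_08,B,1,2,3,28,1,0,34,NA,FALSE,NA
MS_08,B,2,1,2,21,48,0,72,NA,FALSE,NA
MS_08,B,3,0,0,23,20,0,43,NA,FALSE,NA
MS_08,B,4,2,4,20,23,0,49,NA,FALSE,NA
MS_09,B,1,1,4,0,2,0,7,NA,FALSE,NA
MS_09,B,2,0,0,3,10,0,13,NA,FALSE,NA
MS_09,B,3,0,1,1,3,0,5,NA,FALSE,NA
MS_09,B,4,0,4,4,3,0,11,NA,FALSE,NA
MS_10,B,1,3,6,22,4,0,35,39,FALSE,NA
MS_10,B,2,1,6,28,234,0,269,152,FALSE,NA
MS_10,B,3,1,5,23,63,0,92,107,FALSE,NA
MS_10,B,4,3,3,15,90,5,111,NA,FALSE,NA
MS_11,B,1,1,3,16,1,0,21,NA,FALSE,NA
MS_11,B,2,2,1,21,13,0,37,NA,FALSE,NA
MS_11,B,3,0,0,28,1,0,29,NA,FALSE,NA
MS_11,B,4,0,0,11,3,8,14,NA,FALSE,NA
MS_12,B,1,1,1,28,1,0,31,NA,FALSE,NA
MS_12,B,2,1,1,30,63,0,95,NA,FALSE,NA
MS_12,B,3,1,0,15,23,0,39,NA,FALSE,NA
MS_12,B,4,0,0,17,18,0,35,NA,FALSE,NA
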