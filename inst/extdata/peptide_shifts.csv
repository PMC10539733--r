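peptide,residue,position,ca_ppm,cb_ppm,cg_ppm,cd_ppm,hd2_ppm,hd3_ppm,dd_printed_ppm,dca_printed_ppm
MpRS,Pro,1,61.76,30.86,26.51,49.28,3.42,3.37,4.35,-1.58
MpRS,Pro,2,61.62,30.57,27.26,50.37,3.69,3.54,3.31,-1.72
MpRS,Pro,3,61.24,30.49,27.32,50.20,3.80,3.60,3.17,-2.10
MpRS,(4R)-FPro,4,59.72,37.22,95.66,56.52,4.20,3.81,-58.44,-3.62
MpRS,Pro,5,62.86,32.06,27.26,50.51,3.85,3.64,4.80,-0.48
MpRS,Ser,6,56.46,62.97,NA,NA,NA,NA,NA,-2.25
MpRS,Pro,7,61.53,30.78,27.32,50.69,3.82,3.68,3.46,-1.81
MpRS,(4S)-FPro,8,60.35,36.90,95.63,56.50,4.07,3.96,-58.73,-2.99
MpRS,Pro,9,61.22,30.52,27.25,50.13,3.74,3.56,3.27,-2.12
MpRS,Pro,10,61.19,30.73,27.25,50.25,3.82,3.59,3.48,-2.15
MpRS,Pro,11,62.82,32.01,27.26,50.33,3.80,3.59,4.75,-0.52
MpRS,Arg,12,55.80,30.80,26.96,43.17,3.13,3.13,NA,-0.98
MpRS,Val,13,61.83,33.03,NA,NA,NA,NA,NA,-0.71
MpRS,Tyr,14,57.51,39.09,NA,NA,NA,NA,NA,-0.67
MpRS,Lys,15,55.16,32.72,24.63,28.84,1.65,1.62,NA,-1.80
MpSR,Pro,1,61.75,30.91,26.52,49.30,3.42,3.37,4.39,-1.59
MpSR,Pro,2,61.65,30.64,27.27,50.36,3.70,3.54,3.37,-1.69
MpSR,Pro,3,61.31,30.63,27.30,50.28,3.82,3.59,3.33,-2.03
MpSR,(4S)-FPro,4,60.32,36.97,95.09,56.55,4.07,3.99,-58.12,-3.02
MpSR,Pro,5,63.06,31.89,27.27,50.44,3.85,3.62,4.62,-0.28
MpSR,Ser,6,56.24,63.04,NA,NA,NA,NA,NA,-2.47
MpSR,Pro,7,61.51,30.66,27.26,50.50,3.79,3.64,3.40,-1.83
MpSR,(4R)-FPro,8,59.77,37.20,95.10,56.58,4.22,3.84,-57.90,-3.57
MpSR,Pro,9,61.37,30.68,27.29,50.21,3.75,3.61,3.39,-1.97
MpSR,Pro,10,61.26,30.62,27.27,50.32,3.81,3.63,3.35,-2.08
MpSR,Pro,11,62.79,32.01,27.27,50.36,3.79,3.61,4.74,-0.55
MpSR,Arg,12,55.82,30.82,26.94,43.17,3.13,3.13,NA,-0.96
MpSR,Val,13,61.82,33.04,NA,NA,NA,NA,NA,-0.72
MpSR,Tyr,14,57.52,39.09,NA,NA,NA,NA,NA,-0.66
MpSR,Lys,15,55.23,32.74,24.61,28.87,NA,NA,NA,-1.73
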