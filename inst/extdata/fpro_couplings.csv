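source,jfb2,jfb3,jfd2,jfd3,jab2,jab3
MpRS_P4_(4R),42.3,18.8,38.2,21.7,10.1,8.1
MpRS_P8_(4S),21.0,42.5,24.6,35.2,3.0,10.5
MpSR_P4_(4S),20.9,43.1,24.7,35.4,3.1,10.2
MpSR_P8_(4R),42.1,18.9,38.3,21.9,10.2,8.1
free_(4R)-FPro,40.5,19.6,37.4,20.1,10.4,8.1
free_(4S)-FPro,20.5,41.9,19.4,37.6,2.8,10.5
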