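layer,age_months,mean_um,sd_um,n
RNFL-GCL,1,12.90,0.72,104
IPL,1,51.55,2.04,104
INL,1,25.57,1.02,104
OPL,1,15.22,0.30,104
ONL,1,62.13,1.17,104
IS,1,10.79,0.53,104
OS,1,11.61,0.40,104
RPE,1,20.93,1.45,104
TRT,1,210.06,3.09,104
RNFL-GCL,2,13.10,0.89,102
IPL,2,48.04,2.31,102
INL,2,21.93,0.86,102
OPL,2,15.13,0.31,102
ONL,2,60.64,1.38,102
IS,2,11.07,0.57,102
OS,2,11.36,0.47,102
RPE,2,22.89,1.04,102
TRT,2,202.90,3.29,102
RNFL-GCL,3,13.44,0.93,85
IPL,3,47.52,3.19,85
INL,3,21.45,0.89,85
OPL,3,15.12,0.21,85
ONL,3,60.64,1.19,85
IS,3,11.04,0.42,85
OS,3,11.19,0.33,85
RPE,3,23.24,1.23,85
TRT,3,203.34,3.59,85
RNFL-GCL,4,13.48,0.72,103
IPL,4,47.23,1.92,103
INL,4,20.62,0.61,103
OPL,4,15.11,0.23,103
ONL,4,60.15,0.98,103
IS,4,11.21,0.42,103
OS,4,11.14,0.39,103
RPE,4,23.47,0.90,103
TRT,4,200.69,2.40,103
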