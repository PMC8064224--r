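layer,age_months,mean_um,sd_um,n
RNFL-GCL,1,13.15,0.79,94
IPL,1,47.92,2.45,94
INL,1,22.41,0.99,94
OPL,1,14.90,0.31,94
ONL,1,62.09,1.58,94
IS,1,10.18,0.36,94
OS,1,11.29,0.38,94
RPE,1,19.42,0.82,94
TRT,1,200.54,3.83,94
RNFL-GCL,2,13.69,0.87,83
IPL,2,45.59,2.39,83
INL,2,19.63,0.85,83
OPL,2,14.81,0.26,83
ONL,2,60.57,1.80,83
IS,2,10.61,0.38,83
OS,2,11.34,0.50,83
RPE,2,21.46,1.06,83
TRT,2,196.77,3.70,83
RNFL-GCL,3,13.95,0.85,88
IPL,3,45.79,2.30,88
INL,3,19.50,0.62,88
OPL,3,14.92,0.23,88
ONL,3,60.59,1.64,88
IS,3,10.80,0.40,88
OS,3,11.34,0.40,88
RPE,3,21.90,1.01,88
TRT,3,197.68,3.18,88
RNFL-GCL,4,14.03,0.72,84
IPL,4,45.86,2.72,84
INL,4,18.96,0.73,84
OPL,4,14.89,0.27,84
ONL,4,59.86,1.84,84
IS,4,10.97,0.36,84
OS,4,11.43,0.41,84
RPE,4,22.29,1.02,84
TRT,4,196.16,3.14,84
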