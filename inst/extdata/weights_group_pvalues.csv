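age_months,p
1,0.86
2,0.39
3,0.47
4,0.36
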