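group,eye,age_months,n_volumes
WT,OS,1,54
WT,OS,2,52
WT,OS,3,49
WT,OS,4,53
WT,OD,1,50
WT,OD,2,50
WT,OD,3,36
WT,OD,4,50
3xTg-AD,OS,1,46
3xTg-AD,OS,2,41
3xTg-AD,OS,3,43
3xTg-AD,OS,4,40
3xTg-AD,OD,1,48
3xTg-AD,OD,2,42
3xTg-AD,OD,3,45
3xTg-AD,OD,4,44
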