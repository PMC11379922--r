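indicator,units,fn_kind,m1,m2,x1,x2,x3,x4
pH,pH units,parabolic,,,5.5,6.5,7.5,8.5
SOM,g/kg,s_type,4,13,,,,
AN,mg/kg,s_type,5,15,,,,
AP,mg/kg,s_type,3,10,,,,
AK,mg/kg,s_type,100,380,,,,
TP,g/kg,s_type,1,2,,,,
TN,g/kg,s_type,1,2.5,,,,
SMC,%,parabolic,,,5.25,8,10,16
BD,g/kg,parabolic,,,0.55,0.75,0.85,1.25
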