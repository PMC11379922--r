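component,eigenvalue,variance_pct,cumulative_pct
1,5.435,60.392,60.392
2,1.204,13.376,73.769
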