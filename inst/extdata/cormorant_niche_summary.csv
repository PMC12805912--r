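species,season,n,TNW,WIC,BIC,IS,overlap_pct
P_gaimardi,non_breeding,25,1.39,1.09,0.30,0.213,95.7
P_gaimardi,breeding,31,1.09,0.73,0.36,0.324,89.6
L_atriceps,non_breeding,18,3.06,1.36,1.70,0.541,48.3
L_atriceps,breeding,37,2.19,1.94,0.25,0.112,43.7
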