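residue,atom_type,delta_exp,epsilon,delta_calc
1,CA,55.12,0.30,55.40
1,CB,29.88,0.35,29.70
1,C',175.30,0.25,175.95
1,N,119.70,0.40,120.05
1,HN,8.21,0.05,8.15
1,HA,4.32,0.05,4.45
2,CA,58.40,0.30,58.35
2,N,121.10,0.40,122.00
2,HN,8.05,0.05,8.02
3,CA,54.95,0.30,54.20
3,CB,41.20,0.35,41.25
3,HA,4.60,0.05,4.58
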