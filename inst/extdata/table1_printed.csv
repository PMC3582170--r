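quantity,mean,se,mean_dp,se_dp
body_weight_kg,376,47.6,0,1
brain_weight_g,532,25.5,0,1
brain_volume_cm3,510,25.9,0,1
sc_weight_g,249.6,22.7,1,1
sc_length_cm,167.2,7.6,1,1
sc_volume_cm3,247.3,23.1,1,1
csc_weight_g,107.2,10.4,1,1
csc_length_cm,61.2,3.2,1,1
csc_volume_cm3,95.5,8.3,1,1
ratio_csc_sc_weight_pct,42.8,0.4,1,1
ratio_csc_sc_length_pct,36.6,0.3,1,1
ratio_csc_sc_volume_pct,38.7,0.6,1,1
rw_sc_pct,0.068,0.005,3,3
rw_csc_pct,0.029,0.002,3,3
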