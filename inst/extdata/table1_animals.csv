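animal,body_weight_kg,brain_weight_g,brain_volume_cm3,sc_weight_g,sc_length_cm,sc_volume_cm3,csc_weight_g,csc_length_cm,csc_volume_cm3
Pony,230,455,425,207.2,142.9,204.7,87.8,51.4,77.4
Arabian,300,490,475,186.3,156.2,180.3,77.3,56.1,73.5
Belgium,480,570,550,305.9,178.4,297.1,130.8,65.2,111.7
TB_I,420,590,560,267.0,175.6,270.9,116.6,66.0,104.1
TB_II,450,555,540,281.6,182.8,283.7,123.4,67.5,110.8
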