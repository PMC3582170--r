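compartment,mean_ce
total,0.044
wm,0.046
gm,0.046
dh,0.052
vh,0.054
cc,0.053
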