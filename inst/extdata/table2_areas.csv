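segment,gs_mm2,gs_se,gs_letters,wm_mm2,wm_se,wm_letters,gm_mm2,gm_se,gm_letters,dh_mm2,dh_se,dh_letters,vh_mm2,vh_se,vh_letters,cc_1e3_mm2,cc_se,cc_letters
C1,132,9.9,c,115,9.8,b,16.5,0.7,c,10.9,0.7,a,5.6,0.2,cd,58.9,4.3,a
C2,127,8.5,c,115,8.1,b,11.2,0.6,e,6.6,0.4,c,4.6,0.2,e,58.1,3.5,a
C3,120,7.5,c,111,7.3,b,9.1,0.3,f,5.2,0.2,d,3.9,0.2,e,59.1,5.7,a
C4,124,8.6,c,115,8.3,b,9.0,0.3,f,5.1,0.2,d,3.9,0.3,e,53.3,2.6,a
C5,134,8.7,c,123,8.2,ab,10.3,0.5,ef,5.5,0.3,cd,4.7,0.3,de,50.9,5.8,ab
C6,147,10.4,bc,134,9.8,ab,12.8,0.6,d,6.6,0.3,c,6.2,0.4,c,48.7,6.1,ab
C7,169,5.0,ab,147,5.3,a,22.1,0.4,b,9.5,0.3,b,12.6,0.4,b,38.3,4.8,b
C8,175,8.0,a,147,7.7,a,27.8,0.6,a,11.5,0.5,a,16.4,0.4,a,37.1,2.8,b
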