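segment,arc_cm3,arc_se,arc_letters,total_mm3,total_se,total_letters,wm_mm3,wm_se,wm_letters,gm_mm3,gm_se,gm_letters,dh_mm3,dh_se,dh_letters,vh_mm3,vh_se,vh_letters,cc_1e3_mm3,cc_se,cc_letters
C1,5.7,0.4,c,3884,387,c,3402,370,c,483,30,c,319,24,b,164,9,c,1.7,0.12,d
C2,14.2,1.5,ab,10040,1187,a,9159,1114,a,880,80,b,521,49,a,359,34,b,4.5,0.27,abc
C3,17.1,1.8,a,11693,1679,a,10813,1587,a,880,99,b,502,48,a,378,54,b,5.6,0.50,a
C4,16.9,1.8,a,11731,1313,a,10884,1247,a,847,66,b,477,36,a,370,34,b,5.00,0.33,ab
C5,15.9,1.8,ab,11207,1268,a,10349,1187,a,858,82,b,465,53,a,392,36,b,4.2,0.57,bc
C6,14.6,1.3,ab,10387,972,a,9480,915,a,906,59,b,468,36,a,439,28,b,3.5,0.58,c
C7,11.7,0.9,abc,8956,670,ab,7790,621,ab,1167,61,a,503,36,a,664,32,a,2.1,0.33,d
C8,8.9,1.0,bc,6462,5887,bc,5441,527,bc,1022,65,ab,425,41,ab,597,25,a,1.4,0.13,d
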