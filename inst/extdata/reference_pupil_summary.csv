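experiment,participant,max1_mm,min_mm,lum_decrease_pct,max2_mm,lum_increase_pct
blink,P1,2.971,2.834,-9.035,3.044,15.384
blink,P2,3.071,2.717,-21.710,3.072,27.808
blink,P3,3.356,3.153,-11.719,3.287,8.692
blink,P4,3.529,2.877,-33.555,3.034,11.206
saccade,P1,2.979,2.760,-14.169,2.996,17.811
saccade,P2,3.098,2.888,-13.079,3.147,18.745
saccade,P3,3.239,3.071,-10.129,3.252,12.155
saccade,P4,3.292,3.058,-13.723,3.270,14.358
onset,P1,2.973,2.801,-11.201,2.987,13.668
onset,P2,3.096,2.813,-17.471,3.099,21.401
onset,P3,3.486,3.187,-16.386,3.388,13.021
onset,P4,3.088,2.809,-17.297,2.999,13.990
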