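system,term,mean,sd
wt,E_vdw,-68.36,4.36
wt,E_ele,-75.44,31.88
wt,G_polar,97.24,28.18
wt,G_nonpolar,-8.63,0.57
wt,dG_gas,-143.80,32.67
wt,dG_binding,-55.19,7.88
r135k,E_vdw,-61.57,5.49
r135k,E_ele,-37.60,39.73
r135k,G_polar,68.16,35.80
r135k,G_nonpolar,-7.46,0.78
r135k,dG_gas,-99.17,40.27
r135k,dG_binding,-38.47,8.56
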