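subject,group,voi_label,mean_ktrans,mean_rbf
m1,meningioma,tumour,0.075540319,8.182527
m1,meningioma,control,0.001555,0.661594
m2,meningioma,tumour,0.103790104,10.46861
m2,meningioma,control,0.007604,1.27435
m3,meningioma,tumour,0.011755032,2.773495
m3,meningioma,control,0.000313,0.127114
m4,meningioma,tumour,0.031140747,2.008031
m4,meningioma,control,0.006121,0.623004
m5,meningioma,tumour,0.054707296,5.798886
m5,meningioma,control,0.003139,0.797508
m6,meningioma,tumour,0.039027199,2.747369
m6,meningioma,control,0.000417,1.087866
o1,other,tumour,0.019257911,1.62082
o2,other,tumour,0.012620783,1.347984
o3,other,tumour,0.016456641,1.561967
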