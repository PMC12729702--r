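trait,QMg,QMr,k,h2_published,cvg_cve_published,cv_published
FL,37.29,0.55,4,98.51,4.07,2.17
FD,28.71,0.65,4,97.70,3.26,2.60
FFM,74.84,1.81,4,97.57,3.17,6.52
EL,9.47,0.41,4,95.60,2.33,3.27
EW,5.53,0.27,4,94.96,2.17,3.82
ET,3.24,0.24,4,92.32,1.73,4.60
EM,0.16,0.01,4,96.0,2.44,6.87
SE,1061.12,99.40,4,90.63,1.55,42.52
ESI,0.07,0.01,4,91.79,1.67,48.75
MET,720.45,265.81,4,63.10,0.65,36.41
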