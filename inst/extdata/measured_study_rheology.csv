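case,shear_rate_s^-1,flow_rate_m3s^-1,n,mu
01,8,2.19e-8,0.943,0.887
02,17,4.35e-8,0.928,0.816
03,24,6.14e-8,0.860,0.642
04,30,7.86e-8,1.04,1.15
05,39,1.02e-7,0.905,0.705
06,47,1.21e-7,0.850,0.561
07,56,1.46e-7,0.793,0.434
08,62,1.60e-7,0.877,0.602
09,73,1.90e-7,0.874,0.583
10,84,2.18e-7,0.885,0.600
11,97,2.52e-7,0.880,0.578
12,104,2.68e-7,0.918,0.683
13,132,3.42e-7,0.939,0.742
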