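id,status,thickness_mm,width_mm,area_mm2,ultimate_strain,ultimate_stress_MPa
R,unruptured,0.05,3,0.15,1.27639,1.09936
K2,unruptured,0.05,4,0.2,1.5729,1.1314
V,ruptured,0.15,3.75,0.56,1.06323,1.05493
Z,ruptured,0.2,3.3,0.66,0.744889,1.00979
U,ruptured,0.25,3.56,0.91,2.85794,1.00356
K1,unruptured,0.3,5,1.5,4.6129,1.75217
M,ruptured,0.7,4,2.8,1.30277,0.382825
Ul,ruptured,0.6,3.85,2.31,3.96535,0.33317
A1,not_applicable,0.4,3,1.2,1.41559,2.4794
A2,not_applicable,0.2,1,0.2,1.37917,0.141357
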