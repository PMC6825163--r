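id,MR3,MR5,YEOH,NEO_HOOKEAN
K1,5.10488,5.10488,5.10488,3.70363
K2,1.81725,1.81725,1.81725,1.81725
R,2.00078,2.00078,2.00078,2.00078
V,1.60622,2.003,1.32909,1.32909
Z,2.00094,2.00094,2.00094,2.00094
U,2.54697,2.80683,2.54696,1.5161
M,2.20088,2.20088,1.90279,1.90279
Ul,2.53922,2.53922,2.53922,2.53922
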