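id,model,C1,C2,C3,C4,C5
K2,MR3,0.464950,-0.464947,9.17e-7,,
R,MR3,0.313226,-0.313226,1.863e-6,,
V,MR3,0.479274,-0.43089,0.159734,,
Z,MR3,0.204286,0.070981,0.068063,,
U,MR3,0.085436,-0.07656,0.028474,,
K1,MR3,0.029655,0.021101,0.009883,,
M,MR3,0.046188,-0.046162,0.015390,,
Ul,MR3,0.0263132,-0.00878,0.017,,
K2,YEOH,0.021704,0.031802,,,
R,YEOH,2.678e-7,0.032626,,,
V,YEOH,4.77e-7,0.0379351,,,
Z,YEOH,1.12581,0.172556,,,
U,YEOH,7.85e-7,0.007087,,,
K1,YEOH,1.07937e-6,0.007273,,,
M,YEOH,1.25635,0.095805,,,
Ul,YEOH,0.0002,0.000229,,,
K2,NEO_HOOKEAN,0.0615,,,,
R,NEO_HOOKEAN,0.12038,,,,
V,NEO_HOOKEAN,0.100453,,,,
Z,NEO_HOOKEAN,0.123172,,,,
U,NEO_HOOKEAN,0.116763,,,,
K1,NEO_HOOKEAN,0.058434,,,,
M,NEO_HOOKEAN,0.045382,,,,
Ul,NEO_HOOKEAN,0.0099307,,,,
K2,MR5,0.46492,-0.464896,2.552e-6,2.334e-7,-1.598e-6
R,MR5,0.12038,-0.12038,-0.040056,0.040069,-0.000011
V,MR5,0.618282,-0.51001,-0.205882,0.205964,-0.000018
Z,MR5,0.2717,0.0274076,-0.089769,0.090082,-0.000059
U,MR5,0.075683,-0.034887,-0.022802,0.024003,-9.154e-6
K1,MR5,0.056429,0.005771,0.008226,0.000468,-0.00861
M,MR5,0.052108,-0.05119,-0.017356,0.01736,-1.652e-6
Ul,MR5,0.021751,-0.004683,0.0005,0.000782,-0.000699
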