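variable,LBN-UP1,UP1-UP2,UP2-UP3,LBN-OUT1,OUT1-OUT2,OUT2-OUT3,LBN-IN1,IN1-IN2,IN2-MID,LBN-MID4,MID4-MID3,MID3-UP2
age,0.27,0.34,0.32,0.33,0.33,0.27,0.19,0.33,0.30,0.23,0.22,0.35
height,0.23,0.30,0.28,0.35,0.29,0.25,0.26,0.36,0.35,0.31,0.27,0.33
weight,0.26,0.32,0.30,0.38,0.32,0.28,0.32,0.40,0.37,0.36,0.33,0.36
bmi,0.25,0.32,0.30,0.38,0.31,0.27,0.34,0.39,0.38,0.37,0.33,0.34
bra_underband,0.36,0.43,0.41,0.50,0.42,0.38,0.45,0.49,0.52,0.49,0.45,0.45
bra_cup,0.20,0.21,0.21,0.26,0.24,0.23,0.32,0.26,0.28,0.30,0.35,0.21
underbust_girth,0.43,0.50,0.48,0.56,0.49,0.45,0.47,0.56,0.57,0.51,0.47,0.53
breast_circumference,0.40,0.46,0.44,0.55,0.45,0.42,0.53,0.56,0.58,0.57,0.52,0.48
left_across_cup,0.50,0.56,0.54,0.66,0.55,0.53,0.63,0.65,0.68,0.67,0.61,0.58
shoulder_to_lbn,0.49,0.55,0.53,0.65,0.55,0.52,0.62,0.64,0.66,0.68,0.62,0.57
npsn_to_lbn,0.47,0.53,0.51,0.62,0.53,0.50,0.63,0.62,0.65,0.69,0.63,0.55
lbn_to_rbn,0.43,0.46,0.45,0.55,0.48,0.46,0.64,0.55,0.60,0.62,0.63,0.48
left_shoulder_angle,0.45,0.51,0.49,0.53,0.51,0.45,0.46,0.54,0.55,0.47,0.47,0.52
abduction_angle,0.77,0.80,0.80,0.84,0.83,0.81,0.86,0.86,0.85,0.86,0.90,0.80
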