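subject_id,age,height_cm,weight_kg,bmi,cup_size,underbust_girth_cm,breast_circumference_cm,left_across_cup_cm,shoulder_to_lbn_cm,npsn_to_lbn_cm,lbn_to_rbn_cm,left_shoulder_angle_deg
No. 01,54,161,61.2,23.6,C,80.8,94.3,19.8,25.5,20.5,19.4,26.2
No. 02,58,155,63.4,26.4,F,79.7,99.3,22.3,27.6,23.6,22.0,27.5
No. 03,58,153,58.0,24.8,E,83.2,102.0,22.0,25.3,22.1,19.3,25.2
No. 04,65,148,51.4,23.5,C,78.5,92.4,21.1,26.0,22.4,15.4,34.7
No. 05,67,155,67.4,28.1,D,83.5,99.0,19.6,24.5,21.6,19.0,28.1
No. 06,63,149,63.4,28.6,D,89.5,104.5,22.8,26.5,21.5,18.8,22.3
No. 07,63,158,60.2,24.1,C,75.6,88.0,19.6,24.0,19.0,14.9,30.3
No. 08,57,158,57.0,22.8,D,75.5,90.2,20.7,24.5,19.7,15.7,28.2
No. 09,59,163,71.1,26.8,D,83.0,97.0,23.4,28.5,24.3,19.0,26.4
No. 10,68,157,70.1,28.4,C,85.5,97.1,20.5,26.5,22.0,17.2,28.1
No. 11,66,154,54.2,17.2,D,75.0,91.0,20.2,25.0,21.5,15.3,26.0
No. 12,68,152,59.9,25.9,C,84.7,99.0,22.3,26.7,20.1,15.6,28.1
No. 13,58,160,55.5,21.7,C,75.0,86.6,18.6,23.3,18.8,18.0,30.4
No. 14,59,153,63.0,26.9,D,82.5,97.5,21.6,24.0,19.3,18.5,30.3
No. 15,59,144,57.6,27.8,C,80.9,94.8,21.6,25.5,21.0,17.6,31.2
No. 16,69,158,53.7,21.5,D,73.5,89.0,19.0,24.0,20.4,16.8,28.3
No. 17,57,147,57.0,26.4,C,81.7,94.7,20.2,25.0,19.0,14.6,30.9
No. 18,60,160,62.1,24.3,D,88.5,102.6,22.8,29.3,23.6,19.2,29.8
No. 19,66,148,53.1,24.2,C,78.7,90.0,20.7,24.7,20.6,16.3,29.3
No. 20,61,159,56.7,22.4,C,76.5,89.6,19.8,26.1,19.7,15.3,30.3
No. 21,60,160,69.5,27.1,D,87.2,101.2,23.0,28.2,21.5,17.9,27.7
No. 22,62,155,59.4,24.7,D,75.5,90.2,19.8,26.4,22.3,16.7,24.4
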