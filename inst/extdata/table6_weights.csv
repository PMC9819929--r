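w_1,w_2,w_3,w_4,w_5,w_6,w_7,w_8,w_9,w_10,w_11,bias
-4.355,-1.961,6.768,1.038,-13.321,-6.471,17.698,15.025,5.251,1.609,7.369,20.718
-8.956,2.835,23.007,2.499,0.307,-12.118,11.223,12.103,0.959,2.530,8.823,24.272
-10.458,6.771,31.326,2.567,6.966,-12.720,9.051,8.774,4.312,8.023,22.185,20.153
-5.199,2.925,-4.201,-0.526,-2.933,-5.716,10.163,4.422,14.135,4.688,17.431,22.513
-14.029,7.974,3.193,4.999,-3.178,-7.738,14.917,11.048,4.683,6.532,6.536,18.344
-14.104,16.504,-6.633,11.439,23.400,-7.142,6.071,-10.219,11.852,19.494,26.576,8.493
1.565,-2.581,-3.363,-0.683,-3.219,9.362,-2.693,-0.945,10.077,16.910,11.685,25.174
-0.634,-4.802,-6.711,-4.255,-3.403,-8.806,8.082,13.033,-0.356,2.650,5.280,30.560
18.614,-1.278,-5.582,-1.050,12.584,-2.331,-1.303,-9.887,25.511,11.855,27.711,8.702
3.481,-0.781,2.008,-1.307,-2.779,2.778,0.783,-3.568,10.910,9.893,12.617,26.067
2.499,-4.119,9.285,-5.471,6.988,-7.855,4.113,6.572,5.670,10.965,26.380,18.259
-3.797,-4.049,4.465,-2.045,0.101,-11.777,8.836,15.087,-0.798,3.695,10.170,27.366
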