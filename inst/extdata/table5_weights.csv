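w_1,w_2,w_3,w_4,w_5,w_6,w_7,w_8,bias
-0.010,-1.048,1.582,-7.208,2.790,2.177,-0.536,1.289,-52.500
-0.197,-19.367,10.071,-6.369,13.647,19.055,-3.162,5.684,-75.619
-0.014,0.804,0.349,-3.800,-0.027,-0.098,3.652,-5.372,54.097
-0.342,2.342,-1.826,1.545,-3.742,2.360,-2.014,-0.347,63.730
-0.029,4.488,-3.997,1.586,-4.843,2.083,-0.566,0.776,51.040
-0.006,53.724,-41.630,-24.888,-5.534,-33.960,-33.537,51.446,3.809
0.004,9.841,-5.817,-13.680,-8.531,11.753,-2.689,2.603,-1.797
0.000,0.854,-0.451,3.798,-1.362,-2.483,0.950,0.900,-56.760
-0.001,3.257,-1.502,10.777,-3.417,-10.993,5.818,-3.216,-35.393
-0.002,-14.456,18.523,-8.315,-0.696,2.606,-11.888,-7.712,-13.755
-0.004,1.446,-9.972,-11.381,-1.969,33.103,-7.837,17.092,15.084
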