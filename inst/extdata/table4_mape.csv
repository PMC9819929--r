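network,hidden_size,algorithm,mape_pct
N1,6,GDBP,17.7
N2,6,MOBP,15.2
N3,6,CGBP,14.5
N4,6,RPROP,14.5
N5,6,VLN,13.3
N6,7,GDBP,19.6
N7,7,MOBP,16.6
N8,7,CGBP,14.0
N9,7,RPROP,14.0
N10,7,VLN,13.6
N11,8,GDBP,18.9
N12,8,MOBP,17.7
N13,8,CGBP,14.7
N14,8,RPROP,14.7
N15,8,VLN,13.7
N16,9,GDBP,17.5
N17,9,MOBP,16.7
N18,9,CGBP,14.5
N19,9,RPROP,14.8
N20,9,VLN,13.7
N21,10,GDBP,17.8
N22,10,MOBP,15.3
N23,10,CGBP,14.8
N24,10,RPROP,14.8
N25,10,VLN,14.5
N26,11,GDBP,18.5
N27,11,MOBP,15.6
N28,11,CGBP,14.6
N29,11,RPROP,14.5
N30,11,VLN,13.1
N31,12,GDBP,18.2
N32,12,MOBP,16.2
N33,12,CGBP,14.9
N34,12,RPROP,14.9
N35,12,VLN,13.9
N36,13,GDBP,19.7
N37,13,MOBP,18.8
N38,13,CGBP,15.9
N39,13,RPROP,15.9
N40,13,VLN,13.8
N41,14,GDBP,19.3
N42,14,MOBP,18.2
N43,14,CGBP,15.35
N44,14,RPROP,15.2
N45,14,VLN,13.2
N46,15,GDBP,18.9
N47,15,MOBP,18.3
N48,15,CGBP,15.9
N49,15,RPROP,14.9
N50,15,VLN,13.8
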