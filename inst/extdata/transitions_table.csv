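molecule,functional,basis,medium,e01,lambda01,f,mu01_x,mu01_y,mu01_z,mu01_tot
bixin,B3LYP,"6-31+G(d,p)",gas,2.249,551.32,3.363,-19.844,0.109,-0.003,19.845
isobixin,B3LYP,"6-31+G(d,p)",gas,2.229,556.16,3.591,-20.536,1.552,0.017,20.594
norbixin,B3LYP,"6-31+G(d,p)",gas,2.249,551.35,3.379,19.883,-0.605,0.004,19.892
isonorbixin,B3LYP,"6-31+G(d,p)",gas,2.229,556.23,3.620,-20.635,1.344,0,20.679
bixin,B3LYP,"6-31+G(d,p)",chloroform,2.013,616.07,3.542,-21.528,0.061,-0.013,21.528
isobixin,B3LYP,"6-31+G(d,p)",chloroform,1.994,621.91,3.773,-22.258,-1.707,0,22.323
norbixin,B3LYP,"6-31+G(d,p)",chloroform,2.006,618,3.542,21.553,-0.652,0.001,21.563
isonorbixin,B3LYP,"6-31+G(d,p)",chloroform,1.989,623.28,3.75,22.232,-1.477,0,22.281
bixin,CAM-B3LYP,"6-31+G(d,p)",gas,2.831,437.99,3.642,-18.393,0.708,0.003,18.407
isobixin,CAM-B3LYP,"6-31+G(d,p)",gas,2.805,441.98,3.83,-18.837,-2.170,0.028,18.961
norbixin,CAM-B3LYP,"6-31+G(d,p)",gas,2.828,438.39,3.643,18.380,-1.165,0.012,18.417
isonorbixin,CAM-B3LYP,"6-31+G(d,p)",gas,2.804,442.23,3.791,18.767,-1.972,0.026,18.870
bixin,CAM-B3LYP,"6-31+G(d,p)",chloroform,2.624,472.53,3.802,-19.520,-0.762,0,19.535
isobixin,CAM-B3LYP,"6-31+G(d,p)",chloroform,2.599,477.03,3.970,19.914,-2.393,0.025,20.057
norbixin,CAM-B3LYP,"6-31+G(d,p)",chloroform,2.616,473.92,3.800,19.515,-1.299,0.006,19.558
isonorbixin,CAM-B3LYP,"6-31+G(d,p)",chloroform,2.591,478.54,3.939,19.890,2.166,0.018,20.008
bixin,M06,"6-31+G(d,p)",gas,2.320,534.5,3.391,-19.617,0.313,-0.009,19.619
isobixin,M06,"6-31+G(d,p)",gas,2.298,539.43,3.612,20.260,-1.819,0.027,20.342
norbixin,M06,"6-31+G(d,p)",gas,2.317,535.1,3.403,19.650,-0.774,0.006,19.665
isonorbixin,M06,"6-31+G(d,p)",gas,2.301,538.76,3.578,20.168,-1.626,0.025,20.234
bixin,M06,"6-31+G(d,p)",chloroform,2.090,593.12,3.547,-21.135,0.316,-0.032,21.137
isobixin,M06,"6-31+G(d,p)",chloroform,2.069,599.32,3.762,21.789,-2.031,0.026,21.884
norbixin,M06,"6-31+G(d,p)",chloroform,2.086,594.51,3.547,21.144,0.881,-0.017,21.163
isonorbixin,M06,"6-31+G(d,p)",chloroform,2.065,600.4,3.732,21.741,1.800,0.016,21.816
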