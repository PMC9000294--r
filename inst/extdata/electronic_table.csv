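molecule,functional,basis,medium,homo,lumo,gap,lumo_corrected,erratum
bixin,B3LYP,"6-31+G(d,p)",chloroform,-5.221,-3.073,2.148,-3.073,FALSE
bixin,CAM-B3LYP,"6-31+G(d,p)",chloroform,-6.360,-1.853,4.507,-1.853,FALSE
bixin,M06,"6-31+G(d,p)",chloroform,-5.428,-2.889,2.538,-2.889,FALSE
isobixin,B3LYP,"6-31+G(d,p)",chloroform,-5.220,-3.099,2.121,-3.099,FALSE
isobixin,CAM-B3LYP,"6-31+G(d,p)",chloroform,-6.353,-1.879,4.474,-1.879,FALSE
isobixin,M06,"6-31+G(d,p)",chloroform,-5.426,-2.918,2.508,-2.918,FALSE
norbixin,B3LYP,"6-31+G(d,p)",chloroform,-5.244,-3.104,2.141,-3.104,FALSE
norbixin,CAM-B3LYP,"6-31+G(d,p)",chloroform,-6.379,-1.879,4.499,-1.879,FALSE
norbixin,M06,"6-31+G(d,p)",chloroform,-5.447,-2.915,2.532,-2.915,FALSE
isonorbixin,B3LYP,"6-31+G(d,p)",chloroform,-5.249,-3.134,2.115,-3.134,FALSE
isonorbixin,CAM-B3LYP,"6-31+G(d,p)",chloroform,-6.376,1.911,4.465,-1.911,TRUE
isonorbixin,M06,"6-31+G(d,p)",chloroform,-5.450,-2.948,2.503,-2.948,FALSE
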