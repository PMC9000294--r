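molecule,functional,basis,medium,bla
bixin,B3LYP,"6-31+G(d,p)",gas,0.077
isobixin,B3LYP,"6-31+G(d,p)",gas,0.076
norbixin,B3LYP,"6-31+G(d,p)",gas,0.076
isonorbixin,B3LYP,"6-31+G(d,p)",gas,0.074
bixin,CAM-B3LYP,"6-31+G(d,p)",gas,0.101
isobixin,CAM-B3LYP,"6-31+G(d,p)",gas,0.100
norbixin,CAM-B3LYP,"6-31+G(d,p)",gas,0.100
isonorbixin,CAM-B3LYP,"6-31+G(d,p)",gas,0.100
bixin,M06,"6-31+G(d,p)",gas,0.080
isobixin,M06,"6-31+G(d,p)",gas,0.079
norbixin,M06,"6-31+G(d,p)",gas,0.079
isonorbixin,M06,"6-31+G(d,p)",gas,0.079
bixin,B3LYP,"6-31+G(d,p)",chloroform,0.073
isobixin,B3LYP,"6-31+G(d,p)",chloroform,0.072
norbixin,B3LYP,"6-31+G(d,p)",chloroform,0.073
isonorbixin,B3LYP,"6-31+G(d,p)",chloroform,0.072
bixin,CAM-B3LYP,"6-31+G(d,p)",chloroform,0.098
isobixin,CAM-B3LYP,"6-31+G(d,p)",chloroform,0.097
norbixin,CAM-B3LYP,"6-31+G(d,p)",chloroform,0.098
isonorbixin,CAM-B3LYP,"6-31+G(d,p)",chloroform,0.097
bixin,M06,"6-31+G(d,p)",chloroform,0.077
isobixin,M06,"6-31+G(d,p)",chloroform,0.076
norbixin,M06,"6-31+G(d,p)",chloroform,0.076
isonorbixin,M06,"6-31+G(d,p)",chloroform,0.076
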