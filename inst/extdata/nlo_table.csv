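molecule,functional,basis,medium,mu,alpha,betavec
bixin,B3LYP,"6-31+G(d,p)",gas,5.81,116.14,122.65
bixin,CAM-B3LYP,"6-31+G(d,p)",gas,5.10,89.31,67.83
bixin,M06,"6-31+G(d,p)",gas,5.73,110.94,104.58
isobixin,B3LYP,"6-31+G(d,p)",gas,6.94,121.86,104.85
isobixin,CAM-B3LYP,"6-31+G(d,p)",gas,6.42,92.34,47.23
isobixin,M06,"6-31+G(d,p)",gas,6.75,116.07,86.1
norbixin,B3LYP,"6-31+G(d,p)",gas,5.91,114.35,87.68
norbixin,CAM-B3LYP,"6-31+G(d,p)",gas,5.36,87.66,51.87
norbixin,M06,"6-31+G(d,p)",gas,5.77,109.37,78.67
isonorbixin,B3LYP,"6-31+G(d,p)",gas,2.81,119.66,4.56
isonorbixin,CAM-B3LYP,"6-31+G(d,p)",gas,5.25,90.01,24.85
isonorbixin,M06,"6-31+G(d,p)",gas,5.48,113.08,51.21
bixin,B3LYP,"6-31+G(d,p)",chloroform,6.91,160.85,371.31
bixin,CAM-B3LYP,"6-31+G(d,p)",chloroform,5.73,112.98,144.21
bixin,M06,"6-31+G(d,p)",chloroform,6.72,151.08,284.73
isobixin,B3LYP,"6-31+G(d,p)",chloroform,8.29,168.52,262.47
isobixin,CAM-B3LYP,"6-31+G(d,p)",chloroform,7.52,116.22,76.87
isobixin,M06,"6-31+G(d,p)",chloroform,7.92,158.06,195.13
norbixin,B3LYP,"6-31+G(d,p)",chloroform,7.06,159.6,276.48
norbixin,CAM-B3LYP,"6-31+G(d,p)",chloroform,6.13,111.52,117.24
norbixin,M06,"6-31+G(d,p)",chloroform,6.94,149.76,218.19
isonorbixin,B3LYP,"6-31+G(d,p)",chloroform,6.66,166.67,141.87
isonorbixin,CAM-B3LYP,"6-31+G(d,p)",chloroform,6.28,114.40,37.08
isonorbixin,M06,"6-31+G(d,p)",chloroform,6.53,155.75,111.75
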