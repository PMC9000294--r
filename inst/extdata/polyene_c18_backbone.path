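# canonical 9-double/8-single polyene backbone path (1-based atom indices)
1 2 double
2 3 single
3 4 double
4 5 single
5 6 double
6 7 single
7 8 double
8 9 single
9 10 double
10 11 single
11 12 double
12 13 single
13 14 double
14 15 single
15 16 double
16 17 single
17 18 double
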