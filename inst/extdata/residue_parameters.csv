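residue,lambda,sigma,charge,mass
A,0.2743,0.504,0,71.0788
R,0.7307,0.656,1,156.1875
N,0.4255,0.568,0,114.1038
D,0.0416,0.558,-1,115.0886
C,0.5615,0.548,0,103.1388
Q,0.3934,0.602,0,128.1307
E,0.0006,0.592,-1,129.1155
G,0.7058,0.450,0,57.0519
H,0.4663,0.608,0,137.1411
I,0.5423,0.618,0,113.1594
L,0.6440,0.618,0,113.1594
K,0.1790,0.636,1,128.1741
M,0.5308,0.618,0,131.1926
F,0.8672,0.636,0,147.1766
P,0.3593,0.556,0,97.1167
S,0.4625,0.518,0,87.0782
T,0.3713,0.562,0,101.1051
W,0.9893,0.678,0,186.2132
Y,0.9774,0.646,0,163.1760
V,0.2083,0.586,0,99.1326
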