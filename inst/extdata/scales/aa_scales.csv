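residue,kyte_doolittle,boman,mass_avg
A,1.8,-1.81,71.0788
R,-4.5,14.92,156.1875
N,-3.5,6.64,114.1038
D,-3.5,8.72,115.0886
C,2.5,-1.28,103.1388
Q,-3.5,5.54,128.1307
E,-3.5,6.81,129.1155
G,-0.4,-0.94,57.0519
H,-3.2,4.66,137.1411
I,4.5,-4.92,113.1594
L,3.8,-4.92,113.1594
K,-3.9,5.55,128.1741
M,1.9,-2.35,131.1926
F,2.8,-2.98,147.1766
P,-1.6,0.0,97.1167
S,-0.8,3.40,87.0782
T,-0.7,2.57,101.1051
W,-0.9,-2.33,186.2132
Y,-1.3,0.14,163.1760
V,4.2,-4.04,99.1326
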