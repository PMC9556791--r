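# Random-coil 13C chemical shifts (ppm, DSS-referenced) for the 20 standard
# amino acids, Wishart-style random-coil reference values.
# cb is empty (NA) for glycine, which has no C-beta.
residue,aa,ca,cb,co
A,Ala,52.5,19.1,177.8
R,Arg,56.0,30.9,176.3
N,Asn,53.1,38.9,175.2
D,Asp,54.2,41.1,176.3
C,Cys,58.2,28.0,174.6
Q,Gln,55.7,29.4,176.0
E,Glu,56.6,29.9,176.6
G,Gly,45.1,NA,174.9
H,His,55.0,29.0,174.1
I,Ile,61.1,38.8,176.4
L,Leu,55.1,42.4,177.6
K,Lys,56.2,33.1,176.6
M,Met,55.4,32.9,176.3
F,Phe,57.7,39.6,175.8
P,Pro,63.3,31.7,177.3
S,Ser,58.3,63.8,174.6
T,Thr,61.8,69.8,174.7
W,Trp,57.5,29.6,176.1
Y,Tyr,57.9,38.8,175.9
V,Val,62.2,32.9,176.3
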