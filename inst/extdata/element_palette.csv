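symbol,red,green,blue,vdw_radius,cov_radius
H,1.00,1.00,1.00,1.20,0.31
He,0.85,1.00,1.00,1.40,0.28
Li,0.80,0.50,1.00,1.82,1.28
B,1.00,0.71,0.71,1.92,0.84
C,0.35,0.35,0.35,1.70,0.76
N,0.19,0.31,0.97,1.55,0.71
O,1.00,0.05,0.05,1.52,0.66
F,0.56,0.88,0.31,1.47,0.57
Na,0.67,0.36,0.95,2.27,1.66
Mg,0.54,1.00,0.00,1.73,1.41
Si,0.94,0.78,0.63,2.10,1.11
P,1.00,0.50,0.00,1.80,1.07
S,1.00,1.00,0.19,1.80,1.05
Cl,0.12,0.94,0.12,1.75,1.02
K,0.56,0.25,0.83,2.75,2.03
Ca,0.24,1.00,0.00,2.31,1.76
Fe,0.88,0.40,0.20,2.04,1.32
Zn,0.49,0.50,0.69,2.10,1.22
Br,0.65,0.16,0.16,1.85,1.20
I,0.58,0.00,0.58,1.98,1.39
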