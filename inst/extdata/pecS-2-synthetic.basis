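# SYNTHETIC stand-in for the level-2 property-energy consistent shielding
# basis set. The published exponents/coefficients live in the originating
# supplementary material and are not redistributed; this file reproduces the
# contraction SCHEME and function counts only (H: [3s2p1d] = 14 functions,
# C: [5s4p2d1f] = 34 functions) with invented even-tempered exponents and
# placeholder coefficients. Suitable for structural operations and parsing
# tests, NOT for quantum-chemistry calculations.
H
s 6 3
9.0000000000000000e+01  8.0000000000000000e-03  0.0000000000000000e+00  0.0000000000000000e+00
1.3500000000000000e+01  6.0000000000000000e-02  0.0000000000000000e+00  0.0000000000000000e+00
3.1000000000000000e+00  2.4000000000000000e-01  0.0000000000000000e+00  0.0000000000000000e+00
8.5000000000000000e-01  5.0000000000000000e-01  0.0000000000000000e+00  0.0000000000000000e+00
2.6000000000000000e-01  0.0000000000000000e+00  1.0000000000000000e+00  0.0000000000000000e+00
9.0000000000000000e-02  0.0000000000000000e+00  0.0000000000000000e+00  1.0000000000000000e+00
p 3 2
2.8000000000000000e+00  3.5000000000000000e-01  0.0000000000000000e+00
9.5000000000000000e-01  5.8000000000000000e-01  0.0000000000000000e+00
2.9000000000000000e-01  0.0000000000000000e+00  1.0000000000000000e+00
d 1 1
1.1000000000000000e+00  1.0000000000000000e+00

C
s 10 5
2.5000000000000000e+04  4.0000000000000000e-04  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
3.8000000000000000e+03  3.0000000000000000e-03  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
8.6000000000000000e+02  1.6000000000000000e-02  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
2.4000000000000000e+02  6.5000000000000000e-02  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
7.7000000000000000e+01  2.1000000000000000e-01  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
2.7000000000000000e+01  4.3000000000000000e-01  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
9.8000000000000000e+00  0.0000000000000000e+00  1.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
2.3000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00  1.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
6.2000000000000000e-01  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00  1.0000000000000000e+00  0.0000000000000000e+00
1.9000000000000000e-01  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00  1.0000000000000000e+00
p 7 4
6.0000000000000000e+01  2.0000000000000000e-02  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
1.4000000000000000e+01  1.1000000000000000e-01  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
4.2000000000000000e+00  3.6000000000000000e-01  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
1.3500000000000000e+00  5.5000000000000000e-01  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
4.6000000000000000e-01  0.0000000000000000e+00  1.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
1.5500000000000000e-01  0.0000000000000000e+00  0.0000000000000000e+00  1.0000000000000000e+00  0.0000000000000000e+00
5.0000000000000000e-02  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00  1.0000000000000000e+00
d 2 2
1.9000000000000000e+00  1.0000000000000000e+00  0.0000000000000000e+00
4.8000000000000000e-01  0.0000000000000000e+00  1.0000000000000000e+00
f 1 1
1.0000000000000000e+00  1.0000000000000000e+00
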