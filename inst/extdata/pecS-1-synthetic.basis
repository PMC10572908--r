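# SYNTHETIC stand-in for the level-1 property-energy consistent shielding
# basis set. The published exponents/coefficients live in the originating
# supplementary material and are not redistributed; this file reproduces the
# contraction SCHEME and function counts only (H: [2s1p] = 5 functions,
# C: [4s3p1d] = 18 functions) with invented even-tempered exponents and
# placeholder coefficients. Suitable for structural operations and parsing
# tests, NOT for quantum-chemistry calculations.
H
s 4 2
1.3000000000000000e+01  6.0000000000000000e-02  0.0000000000000000e+00
2.0000000000000000e+00  4.0000000000000000e-01  0.0000000000000000e+00
4.5000000000000000e-01  6.5000000000000000e-01  0.0000000000000000e+00
1.2000000000000000e-01  0.0000000000000000e+00  1.0000000000000000e+00
p 2 1
1.4000000000000000e+00  5.5000000000000000e-01
3.5000000000000000e-01  6.0000000000000000e-01

C
s 7 4
5.0000000000000000e+03  2.0000000000000000e-03  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
7.5000000000000000e+02  1.5000000000000000e-02  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
1.7000000000000000e+02  8.0000000000000000e-02  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
4.7000000000000000e+01  2.9000000000000000e-01  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
1.5000000000000000e+01  0.0000000000000000e+00  1.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
1.8000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00  1.0000000000000000e+00  0.0000000000000000e+00
5.5000000000000000e-01  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00  1.0000000000000000e+00
p 5 3
2.0000000000000000e+01  4.0000000000000000e-02  0.0000000000000000e+00  0.0000000000000000e+00
4.5000000000000000e+00  2.2000000000000000e-01  0.0000000000000000e+00  0.0000000000000000e+00
1.4000000000000000e+00  5.2000000000000000e-01  0.0000000000000000e+00  0.0000000000000000e+00
4.5000000000000000e-01  0.0000000000000000e+00  1.0000000000000000e+00  0.0000000000000000e+00
1.4000000000000000e-01  0.0000000000000000e+00  0.0000000000000000e+00  1.0000000000000000e+00
d 1 1
8.0000000000000000e-01  1.0000000000000000e+00
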