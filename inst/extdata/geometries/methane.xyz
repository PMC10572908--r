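5
methane: synthetic equilibrium geometry, hybrid-DFT/triple-zeta-quality bond lengths; regenerate with a GIAO-DFT engine
C   0.0000000000  0.0000000000  0.0000000000
H   0.6275797426  0.6275797426  0.6275797426
H   0.6275797426 -0.6275797426 -0.6275797426
H  -0.6275797426  0.6275797426 -0.6275797426
H  -0.6275797426 -0.6275797426  0.6275797426
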