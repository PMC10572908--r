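4
acetylene: synthetic equilibrium geometry, hybrid-DFT/triple-zeta-quality bond lengths; regenerate with a GIAO-DFT engine
C   0.0000000000  0.0000000000  0.6010000000
C   0.0000000000  0.0000000000 -0.6010000000
H   0.0000000000  0.0000000000  1.6630000000
H   0.0000000000  0.0000000000 -1.6630000000
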