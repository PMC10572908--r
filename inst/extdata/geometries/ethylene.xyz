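6
ethylene: synthetic equilibrium geometry, hybrid-DFT/triple-zeta-quality bond lengths; regenerate with a GIAO-DFT engine
C   0.6635000000  0.0000000000  0.0000000000
C  -0.6635000000  0.0000000000  0.0000000000
H   1.2272324217  0.9235419627  0.0000000000
H   1.2272324217 -0.9235419627  0.0000000000
H  -1.2272324217  0.9235419627  0.0000000000
H  -1.2272324217 -0.9235419627  0.0000000000
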