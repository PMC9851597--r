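-0.8,0.31,0,0,-0.12
-0.55,-0.6,0.2,0,0
0,0.47,-0.95,-0.33,0
0,0,0.18,-0.7,0.25
0.09,0,0,-0.41,-0.85
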