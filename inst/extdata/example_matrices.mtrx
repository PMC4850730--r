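#INCLUSive Motif Model
#ID = GATA_ppm
#W = 6
0.30 0.05 0.05 0.60
0.05 0.05 0.85 0.05
0.85 0.05 0.05 0.05
0.05 0.05 0.05 0.85
0.85 0.05 0.05 0.05
0.45 0.05 0.45 0.05
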