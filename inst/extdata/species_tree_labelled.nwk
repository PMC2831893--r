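((((mouse:0.04,(retro1#1:0.025,retro2#1:0.025)#1:0.02):0.05,rat:0.08):0.045,((human:0.01,chimp:0.01):0.015,macaca:0.03):0.05):0.02,(cow:0.08,dog:0.08):0.06);
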