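(((retro1#1:0.01,retro2#1:0.01)#1:0.01,mouse:0.02):0.02,rat:0.04);
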