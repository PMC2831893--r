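>rat
ATAACGGCGCTG
>mouse
ATAACGGCGCTG
>retro1
ATAACAGTGCTG
>retro2
CTAATGGCGGTG
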