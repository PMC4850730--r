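>GATA
WGATAR
>Ebox
CANNTG
>Wbox
TTGACY
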