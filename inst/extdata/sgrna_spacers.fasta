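>AAVS1 sgRNA spacer
GGGGCCACTAGGGACAGGAT
>HEK2 sgRNA spacer
GAACACAAAGCATAGACTGC
>HEK3 sgRNA spacer
GGCCCAGACTGAGCACGTGA
>CFex11 sgRNA spacer
CAAAGCATGCCAACTAGAAG
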