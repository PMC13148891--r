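>qPCR_sgRNA_fw scaffold-specific forward primer
TGCTGGAAACAGCATAGCAAGTTT
>qPCR_sgRNA_rv scaffold-specific reverse primer
GACTCGGTGCCACTTTTTCAAGTT
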