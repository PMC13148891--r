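>qPCR_HEK2std scaffold standard oligonucleotide (HEK2 spacer)
AAAAAAAGCACCGACTCGGTGCCACTTTTTCAAGTTGATAACGGACTAGCCTTATTTAAA
CTTGCTATGCTGTTTCCAGCATAGCTCTTAAACGCAGTCTATGCTTTGTGTTC
>qPCR_HEK3std scaffold standard oligonucleotide (HEK3 spacer)
AAAAAAAGCACCGACTCGGTGCCACTTTTTCAAGTTGATAACGGACTAGCCTTATTTAAA
CTTGCTATGCTGTTTCCAGCATAGCTCTTAAACTCACGTGCTCAGTCTGGGCC
>qPCR_CFex11std scaffold standard oligonucleotide (CFex11 spacer)
AAAAAAAGCACCGACTCGGTGCCACTTTTTCAAGTTGATAACGGACTAGCCTTATTTAAA
CTTGCTATGCTGTTTCCAGCATAGCTCTTAAACCTTCTAGTTGGCATGCTTTG
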