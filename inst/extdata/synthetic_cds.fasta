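>synthetic_dfr_cds synthetic stand-in coding sequence (636 nt) for tests and examples
ATGCGAATAGTAAGTCAAAAGGTCTCACCTGACTTAACCAACGTTGAAATCTGTACTAAG
TCCCGTACGTGCGCCTGGGGTTTACCTATGCGCTTGCTGGGGCGAATCAGCTCGCCAATA
TACATCTGTAATTATAAGGCCCGATATGCCCAGACCGCGTATAAGGTGCGACTGCTTAAA
TGCCCGTCACGCCTGACGTTAATATCCAGTATCGCTTCACCTACCTGTAGCGGGGCAACC
TGCAAGGGCCTTGGTAAACTTGCCCATTACTTGCCATATGGCGCATCTGTGCCGAAACCG
GCTGCGACTGAGAGACGTATGACAAGCACTTCGAACATTACGGTGAGTCTTTTAACTACG
CTCGGAACCGCCCACGTGAAGTGTTGGTACTGCAGGTGTGCCGTCCGGGCTCAGCGTGGG
ATCGGACGTCTCGTCGCGGTCTTAACTAAAGATAAGGGACAGCAAGTGTACTCCGTTTTT
GCCCCCGAGCAATTTCTTAGAACTTGGTCGCATATAGGAGGGTGCAGAGGACGCTTTGCC
TACCCGCCTACTAGTCACGGGCGATGGCTCCTCCCCAGTACCTTGTTTTTATTTCCTCTA
ATATCACCATGCAAACAATTTCCAAATCGCGCTTAA
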