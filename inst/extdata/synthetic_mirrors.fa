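>syn_eif5a_mirror
GCCGCCACCGATGGGAGTCGTCCTGCCTTTGCAATGGATGCCGGGCGTTTCGCTCACAAAAAATGTGCGAGTCAAGCTATATTTGAGGTTCTGCTACATTCAGGTTCCTTTCTTTTCTTTTCCCCTTTCCCTCCCCCTTTCCCCTCTCTTTTCCCCCCCTTTCCCTCCCTCCCTCCCTCTTTTCCTTCCCTCTTTTCAGTCTACGTCGGCGTATGGTGCACTGATTACACAAAGTCTAAACGTGCGAGTGTCTCAGTACAACGGCCGTACAAGTGACGTGAGAAATCGGTAATAATAGTGACCTT
>syn_hnrnpc_mirror
AGGCGGCAGAATGGTTGTTCCGCCGGACTACGGTCGAACTACCAGGGAGGTTTTAGGTTTATACGAGACAATCTTCGAAACGTGTTTTCTTGCCCAGCCACCTATGATAACGGTCTCTCTGGGGCGTGTATATGTTTTCTCTCTCTCTCTCCTTTCTTCCTTCTTTTTTCAGCATTCCTATTGGTTAAGAACAAGAGGCACATTAGAGCGGTGGGCCGATGTGTTCGTATTAAGCAATTGCGCGATGGCACAGGAATTATACCCACAGCGCACCTTGAAGGTCGAACCCCAATAATAATAGTGATCCT
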