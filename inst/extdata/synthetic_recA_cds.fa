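>synthetic_recA_cds constructed stand-in; window codons 79-137 encode the named selection residues
ATGATCAGAAATTTCACTCCTTATCCCAACGGAAGGTTTGGGCTTTACCCCCTAAATCAA
CTCGAGGGGTCGCTGGATATTGGCGTAGGGAGACCCGTACGGAGGGTTGTTATGCTCCCA
CGGGGAACTTATACTCATACCTATGTCCGGCCTAAAGTAAAGTGCGTCACTTTCAGGTTA
TCCACGCAGTGCCGTGCACGATTAATTGAGAAAGGTGTGTTGTGCATCACACTAGTGATA
GCTTTAGAGGTGATTGAAGCGAGCGCTTGCAACGTCATCTTTGAACCCCATTATAACGAT
CTGATTGGGGCACCCCGGAATCACGGAGATTGTGACAATTACCCGAGGACCAGGAGAGCG
ACTTCCCGGAGAATCTTCGAGAAGTGTCAAGCACTGGGAAACCACGGCGCGAGGACGGTC
TTACTGCTAGCATGGTGGCTCGAAATACAAGTGTTAGACCCGCGGCCGGTCACTTTTCCT
TTTATGCAGGGTCCCGCAGTGCATATGAGAAGTAGGCCGTCAGACTTTGGTTCGAACAAA
CACTACGTATGCCGCGGTTTAGTACCCAGGTATCATCGATGGAGGAGTTCCGTGTGCCCA
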