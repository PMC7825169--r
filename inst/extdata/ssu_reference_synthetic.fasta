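>ssu_ref_synthetic synthetic 16S rRNA region reference (1450 nt)
AGAGTTTGATCATGGCTCAGATCACCAGGGATCCGACACGGATTTATTCGTAGTTGCTAATTTGCTCTCC
GGCCGGCCAAGCGTCCTGGTTAACTAGGTCTCCCGCTAATCGATCCCGAGTAGTCAATAGGGTGAACAGC
TCCATTGACCCTCGTTACGTTAGGGTATCACAAGGCCCTGTAGCACTCATCAGCGACCCTTCAGGGCATC
AGAGTTGGGATAAATTTCCACCAAACTTCGACCGAGAGTATGGACAGGGCAAAATCTACTATGCCGCGCG
CGTTATAGCTATGCCGACGGCCCAGTGCGCCCGTGACTAGAAATTTTCACGGGAACTCTCCGGGATATAT
ACGTGTCTCTTAGGCTACACGGTGCGGACGACATAGAAACAGAACCCAGTGAAGAGTCGGCAGAGTCCGC
ATGCCCTGAAAACGGTTGCTAGGTCTCCCTTGAGATGCGAAACTTCGCCAAATGCCCCAAGCAGCATGAA
AGTGGATCCTCCAAGCAACGTTTCCGACATGAGCCTTTTTAGCGTGCGATACCTTACGCAGGCTGCAAAG
TTCTAACAAATAGCTCTCGCCTACGGGAATGTTGCCATGAGACTCTTTCTGTACCACCGGTTCGCGTCGG
GGGCTCGCCTCTCAACCAATATTTTCGCAAGGCTCGAATAACGACTCGGGCGGAGACCCCAGTCATCGAA
TCCTGTATGCCGTCGCGCCTGTCCCTGTACCAGCCCGTTGCAGTCATTCTTTCCAATACTCCGCCGGCCA
TAAAAATGCGGTCCTACTTCTTGTTCCGCAATCCATGCCAGGCACCGGGCTCGACACCGCGGCAACCGGC
ATCCCGTCCCGATAGCTCCCTCCTTGCTTTATACTCAGAGCTTGCCTACAGTTCCATCGGGTTCAACGTT
AAGGACATAATTATAATCTGGGACCCACTTCTCCTGACGGAGCGCGCCGTTTGAGAGGATCCCTTCAACC
CGACTATTTAGATTAAAGTGGCGATCAGCCTAGATGTTGGGCAAACCGCACCCAGTGGGCCAACAGTAGC
ACTGGCGAACTCGACTCCCCCTCGACCTTGTCGATGGACGCCAGGACTGTCGAATGAATTATCCAGCGCG
GGGGAGGTTTGTCGTCTCACGTTTTCTTAGGATGATAAATGCGCCGATAGAACCGTACGTTGATCGCCGT
CCACCCGGCTTCTTGACCGGGTAACCGTAAGCCTCGTCGCATGAAGAACGTCCTTACAGCGGCCTGGCTT
TAGATGGCAACCTTGCGATATACGCTCTGCCGCAACGAGAAGAGCGACTAACTGGACATCCGCAATCGCT
GGCTCGTGACTCGGAATCCCTAAATCACGCCCCTAGTGAGAGCTTTGGGCCCCGGGGGGTGGGTTATAAT
ATGGCGAATCAGTGTGTGCGAACTGGTGAGCTTGGCCCGCCCACACAGCT
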