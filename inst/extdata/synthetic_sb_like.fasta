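>synthetic_sb_like synthetic 1638-nt SB-like demonstration element
GTCCTGTACGATCAGGTACTCTTAACGCCTTACATTACGATTTAAACGTAATAAGTGTAT
TCACTCATCAATCACGCCGACTCGGGGTACCAACAACCTAGCGAGCCAGAATGTTACTGG
ATTAATAACCGTACGTTGGATACTACAGCCTTGCTTATTCCACAAGCCGCAGATCACGCA
TCCAAAAATGAGCATATCTTCTTCTTAAGTAAAAGGTCGGCAAACGTTGTAAGTATGTTT
AGTGGGTACTTTCTGGCTCCCTTACGTTGGGTCCACGCCCTACGACTTTCATATTCCCGA
TGCAGGTCCCTGCGGCCTTCTACAATTGGGGTCTCAGCAGTAAGCCTGTCTAGGCGAATA
ACTGGGTCCCGAGCGAGTGTGGTAATGCGTTATGGCTCCCTAAATATCGGAGACACGCCC
TTTATTCGGAGTGTCTTTGGTGTTTAAAGAACGTGATGAGTTATGCCACCATTCAGTATC
GAATCAGCTCGCAAGATTGTTATGGGGCCATTAAGCTCGCTGAATTCACGTCGCCGTATC
GGTCGTTGAGCCGCTTATTCCGGTTGGCCGCCCAGTAAAATCAAACCCTGCTAGTCAGCC
GGATGCTGATACTCACTAAGCAAGCTTACATCCGGTAGTACCACAAACGCTGCGCGTTTC
CCTGCCTATAATGCTGGCGCAAGGGATCTCGGTGGACAAATTAGGTGGCGAGACGAACCC
AGGTAGTGCGTCGCGCGACACTACGTCAACGATGTCTCCCCGCAAAATTTGAGACGAACA
GTCATGAGGATAGGGGATGACACATTACATCATGGTGAATACCGGTGCACCTTAGGGCGC
TATTATCAAAGCATTTTATAACAATGGCGCAATTTACGTGATGTCCGTCGAATCTTTAGT
ACGGTCCCTCTTGGTGGGCTTACCGCTAAATGGGTCAGCCGCGAGTCATGATCCCTATAG
ATCTCAGCTCTCGCCCCCTAATAGACCTATAATCAAACAACATGAGCCCTACCGTGCCTC
TCGTCTGCCGAAGCAACCTACGGGAGAAGAATAGGAGGAGCTACCAGATGTGTACACCGC
TCCTCGGCTCTTTACATTAACTCCTTAGGAACCGCCACACATCGAAACGGTGGTTCAATC
CTCCCGAACTAAACCTCACATGCTTTTTGACAAATGAATGCTCGGCTTTCTTACGTAGTT
TCCCTCGTTTCCTGGATTCGATCACGGGGTACACGAGTCAGCCACCCGGGAACACCTGCG
GGCGACCTGTTCTCAATGTCATTACACGCATAACGAGGTGTCACACCAGAAGAGTGCATT
AGCCCAGCAGTAGAGTCCGTCTCTATGACCTATCCTGGTCACATGCTTCCTGCTTAACTC
AAGAGTATCTTAAAGTTTGGATGAATCGCTAACGTTTGCCGACCTTTTACTTAAGAAGAA
GATATGCTCATTTTTGGATGCGTGATCTGCGGCTTGTGGAATAAGCAAGGCTGTAGTATC
CAACGTACGGTTATTAATCCAGTAACATTCTGGCTCGCTAGGTTGTTGGTACCCCGAGTC
GGCGTGATTGATGAGTGAATACACTTATTACGTTTAAATCGTAATGTAAGGCGTTAAGAG
TACCTGATCGTACAGGAC
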