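>synthetic_transposase_cds synthetic fixture back-translation
ATGATGCCTAATCCTTTTTGTGCTATGGAAGGTTTTTGTGTTTGGTTTCGTTCTCATTTA
CGTGCTGAATGGGCTTATCATTATATTTGGGCTTTTTGTTATATTGAAGAAATGATGCGT
ATTCCTGGTATTACTGGTGAAGTTAATCCTATTGGTTCTTCTCGTAATGCTAAATATTCT
GTTGATTGGGCTGGTTATTTTCAATGGCATGGTACTCAAAAAATGACTAAACCTTCTCAT
ATGATGTGTCATCCTAATAAAAATCAATATATGAAAATTGGTTGTGTTCATTTTATTAAT
CGTGTTAATATTAATATTTGGATGATTGATAAACGTGCTCATAATAATATGTCTAAATTA
ACTAATTATCATATGCGTGAAATGGGTTGGTTACAAACTTTACAAGGTACTAATGCTGTT
TTTTGTTTAATTCATTGTTATTCTAATTTAATTCATATTGAACATTATGCTATTTCTGAT
CCTCGTCATGAATATACTTGTGAATTAGAAATGTCTTCTGTTTTTAAACCTGATGCTGAT
ATTCCTGAATTTAAATGTTGGAATATGATGAAAGCTTATCATTTATATGATGTTCAATTT
AATGATTATCATCAAATTGCTTTTTTTGTTTTTCATGGTTTTCCTGATGAATTATTTGAA
GAAGTTTGTTCTCAAATTGATTATATTAAATTTGGTATGGCTGAACATATTCAAGCTTTA
AAAGAACATGATATTAAAATGTGGCGTTATTTAGTTAATCAATATAAAACTTCTGAATTT
TTAGTTAAAAAATCTCCTTTAATGATTTCTTGGGAAGGTCCTAAAAATTGTATGCGTATG
CAATCTACTATGTTTGCTCGTGGTTTTGCTCCTCCTCCTGATAATGAATTTGGTAATGTT
AATCCTTATCGTTTTTCTGAAGCTAAAAATGCTGTTGCTCAATGTTTTATTCGTTATGAT
GGTCGTTGGATGGTTTGGTTTGAAGATAAATAA
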