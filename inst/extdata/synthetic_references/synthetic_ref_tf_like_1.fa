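>reverse_transcriptase
TACATTAATTGGTTTTACAGTCAATTGGCTTGTCACAACCACTGGTGCTTACGCCGGTTTGCTATGAATG
TAGTGCAAATTCAAATGGCAGAGGTGCATTTGGTTATGGAAATGAAGCGTAGAAGGTTCGAAGTTCTAAC
GAAGTATAACTCTATGAAGGCGCCTTTGACATGGAAAGCAAAAGGGGTATGTAACGAATTTTATATGAAG
CCCCGCAAGGTCCAACCGCATTGCCATCGCCAGTGCTTCTTGAGATGCAATGAATTGCGGGACACGACCA
TCTGGTTTGCGGACTTACCACTTAAGCAGAAAATTATCCAAGCGGACATCAAGCAGGGTATAAATTTTGA
GGAATACATG
>rnase_h
GAGTATCGCTTTAATCGCTGTCGTTTACCTTTTATGCATGGTAAGGATTGCGAATATTATCAAATGGAAT
ACAACCGAGGCTTTTACCACCAGAACGGCGCATTCAACAAGCAGTATAACGACCCACCATGTATCAACAA
CTGTGTCATCTTATGTAACCAGGATTTTGGATCGAGCAGGTATGATCAGGGTATAACGAACGCTATGTAC
CGATTTCAGCTGGTCCACCCCCAGAATTGG
>integrase
TTTACGAAAAATTTTAAGTTTGACATTCGCTGCGAGGAATGCGGTTGCCGTGGGACCCATTATAAACAGA
TGAGGCACATTCGGCCCGAAAGAGACTCTATAAAGCTATGGCAAGTGTCGATGTTCGTTTCACCTTCGGT
GTACGATATTACCGGTCATAGACAGCGCCCCGGGAACGGCTCAGTCGTTCATGTTTTTGGGTGTGATACC
GACGATGAACCGTTTGTCCTGCACGGCAAAAAATGTTTCACGAGTAGATCTCTGTGCAATCCTTGGGCTA
GCTTCATGGGCCCTATGTGG
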