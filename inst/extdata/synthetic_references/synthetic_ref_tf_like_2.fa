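>reverse_transcriptase
TACATTAACTGGTATTACAGTCAATTGGCTTGTCACTACCAATGGTGCTTACGCCGGATTGCTATGAATG
TGTTGCAAATTCAAATGGCAGAGATGCATTTGGTTATGGAAATGAAGTGTAGATGGTTCGAATTCCTAAC
GAAGTATAACTCTATGAGGGCGGCTTTGCCGTGGAAAGCAAAAGGGCTATGTAACGAATTTTATATGAAG
ACCCGCAAGGTCCAACCGCATTGTCATGGCCAGTGCTTCTTGAGATGCAATGCGTTGCGCGAAACGACAA
TCTGGTTTGCGGACTTACCACTTAAGCAGAAACTTATCCACGCTGACTTCAAGCAGGGTATAAATTTAGA
GGACTACCTG
>rnase_h
GAGTATCCCTTTAATCGCTGTCGTTTACCTTTTATGCATGCTAAGGGTTGCGAATATTATCAAATGGTAT
ACAACCGATGGTTTTACCACGAGAACGGCGCAAACAACAAACAGTATAACGACGCAGCATGTATGAACAA
TCGTGTAAGCTTATGTAACCAGTATTTTGGATCGGGCTGGTATGATCAGGGTATGATGAAGGCTATCTAC
CGGTTTCACCTGTTCCACCCCCAGAATAGG
>integrase
TTTACGAAAAATTTCAAGTTTGACTTTCACTGCGAGGAATGTGGTTGCCGTGCGACGCACTATTATCGGA
TGTGGCACATTCAGGCCGAAATAAACTCGATGATGCAATGGCAAGTGTCGATGTTCGTTTCGCCTTCGGT
GTACGATAATACCGGTGACAGACAGCGGCCCGGGAACGGCGCAGTCTTTCATGTTTTTGGGTGTGATACC
GACGATGAACCGTTTGTCCTGCACGGCAAAAAATGGTTAACGTGTAGATCTCTGTGCAATCCTTGGGCTA
GCTTCATGGGCCCTATGTGG
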