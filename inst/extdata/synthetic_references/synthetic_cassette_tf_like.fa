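>gag
GCGAAAATCGAACCGTTTCATCGAAACCGTAACTCGCATGGAGTTTGCTGGAGTACATGGAAGCGTGACT
TGTTCTCCTATTGCGGCGAACATGGTTCAAAGACGCAGTGTTACAACATGCTCGTCGAGATGATTCACAA
CGCAGGTAACGCAATCAATATGAATAAAATGATAAACACGTGGCAGATAGCATACATACGCTTGTGGCCA
ATGTGGCATTCAGAGATGAGCGTGACATGTCACCGGCCGGAACCCTTACGAGCCCCTTAC
>protease
AAGATCTTGTGGCAGGACTACGAACCGATGGGGCCCTCGGTTCAAGCGAGAGAAGCGATCTCGTGCTGGT
CGACTTGCCTTAAACGAGCACCCACCATGGGTGATTTCGAGATAAATTGTGCCTCAGGCTACAATCCGAA
GCGCGTAGGGCATGAATGGGAATGCCCAGTAGTTGATGTCCACACTTTTCTCTGGCACGGAGCTATGTGG
>reverse_transcriptase
TACATTAACTGGTATTACAGTCAATTGGCTTGTCACTACCAATGGTGCTTACGCCGGTTTGCTATGAATG
TGGTGCAAATTCAAATGGCAGAGATGCATTTGGTTATGGAAATGAAGTGTAGATGGTTCGAATTCCTAAC
GAAGTATAACTCTATGAGGGCGGCTTTGCCATGGAAAGCAAAAGGGGTATGTAACGAATTTTATATGAAG
ACCCGCAAGGTCCAACCGCATTGCCATCGCCAGTGCTTCTTGAGATGCAATGAATTGCGCGAAACGACAA
TCTGGTTTGCGGACTTACCACTTAAGCAGAAACTTATCCAAGCGGACATCAAGCAGGGTATAAATTTTGA
GGAATACATG
>rnase_h
GAGTATCGCTTTAATCGCTGTCGTTTACCTTTTATGCATGCTAAGGATTGCGAATATTATCAAATGGTAT
ACAACCGATGGTTTTACCACGAGAACGGCGCAAACAACAAACAGTATAACGACGCACCATGTATGAACAA
TTGTGTAATCTTATGTAACCAGGATTTTGGATCGTGCTGGTATGATCAGGGTATGATGAAGGCTATCTAC
CGGTTTCAGCTGTTCCACCCCCAGAATTGG
>integrase
TTTACGAAAAATTTTAAGTTTGACTTTCGCTGCGAGGAATGTGGTTGCCGTGGGACGCACTATAAACAGA
TGTGGCACATTCAGGCCGAAAAAGACTCTATAAAGCAATGGCAAGTGTCGATGTTCGTTTCGCCTTCGGT
GTACGATAATACCGGTCATAGACAGCGCCCCGGGAACGGCTCAGTCTTTCATGTTTTTGGGTGTGATACC
GACGATGAACCGTTTGTCCTGCACGGCAAAAAATGTTTCACGAGGAGATCTCTGTGCAATCCTTGGGCTA
GCTTCATGGGCCCTATGTGG
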