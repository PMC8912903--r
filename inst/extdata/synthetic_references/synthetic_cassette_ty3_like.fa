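>gag
GCTAAGATAGCGTCTTGTGCATGGAATATGAACGAGCATGCTGTTTGCCTCTCCGATTGGCAGCGCGATC
TGTTCTCTTATGTGGGCGAATGTGGGAAAAAGACGCAGTGCTACAATCACTTAAACCGTATGATTTATAA
CGCTGGGAACGCAATATACCAAAATAAAATGATTAACAAGTGGCAACAGGCGAATATCAGGCTCTGGATG
GGCTGGCATTCTGAAATGGTTTGCGGGTGTTGGGGGGTACACCCTCTGCAGGCATGCTAT
>protease
AAAATTTTAATGCTGATATATGAGAATATGTGGATAAGTAATCAGGCTCTCCAAGCACCTTCCGCTTGGG
TGACGTGCCTAAAGCGAGCACCCACAATGGGCGATTTCCAGATACTGTGGAAGTCTGGTTACAACCTCCT
CCGTGTTGGTCACGATTGGGAGTGTCCTGTAGTGGATTCTCATACATTCCTTTGGCATGGACATATGTGG
>reverse_transcriptase
TACATCAATTTATACTATCACCAGGATCGTTGCCACCGCGGATGGTGCCTTCTCGCCTTCGCCATGGGAG
TTGTACAAATCCAAATGGCTGAGATGCACCTGGTAATGGAAATGAAGTGTCAATGGTTTGAGTTCTTGAC
GAAGTACAACTCTATGCGTGCACAACTGCCGTGCAAAGCAGAAGGTTCTTGTCTGGAGTTTTACCAGAAA
ACAATAAAGGTCCAACCGCATGGACACCGCATGTGCTTTCTTCGGTTCAACGAATTACGAGAAAAGATCA
TCTGGAAGGCAGAGGGCCGGAAAAAGCAGAAATCGAAGCAATACGATATAAGACAGGGGGCTAACTTCTA
CGAGTGGATG
>rnase_h
GAGTATTGGTTTATCCGCACCCATCTTCGTTTCATGCAAGCCAAAGACTGCGAATACTATCAGATGGTGT
ATAACAGGTGGTTTTTACACGAAAACTGGGCAATTAACAAGCAATACAAAGCAGCACCGGTTTGCAATAA
CTGTGTAATCGGCTGCTTTTGGTACTTTGGGAAGTGTTGGAATGACCAGGGCATGCATATGGCGATCTAT
CGAGATCAACACTTCCATCCACAGAATTGG
>integrase
TTTAAGAAGAATTTTTACTTTGACTTCCGGGAAGAATTTAAGGGGTGTCGTGGAACGCACTATAAAATGA
TGTGGCACATCTGGGCTGAATTTTTGTCCATAAAGCAATGGCTCAAGAGCATGACTGTTAATTGTTCCGT
ATATGATAACACAACTCATCTCCAGCGCCCCGGGAATGGTAGTTTCTTTCACGTAGAGCGCTGTGACACT
GAGATGAGAAAATTTGTTCTGGAAGGGCATAACGACTTTACTAGGATTTCACTACAAAAGCTCGAAGCCT
TCCCAATGGGCGCTGACTCT
>chromodomain
AGTTACTATGTGGATTGTTGGATTTGGAATCTGGAAAATAATCTGCCGGAGAAGGGATTAAATGCTAACA
AAAATGCCAATTATCTGCAATTTCAAAAGTATATACCAGCAAGGCAGAAAATGCGCCACGTTGGGTCAGA
GCGACAATGG
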