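>reverse_transcriptase
TACATCAATTTATACTATAACCAGGATCGTTGCCAACGCGGATGGTGCCTTCTCGCCTTCGCCATGGGAG
TTGTACAAATCCAAATGGCTGAGATGCACCTGGTAATGGAAATGAAGTGTCAATGGTTTGAGTTCTTGAC
GAAGCACAACTCTATGCGTGCACAACTGCCGTGCAAAGCAGAAGGTTCTCGTCTGGAGTTTTACCAGAAA
ACAATCAATGTCCAACCGCATGGACACCGTATGTGCTTTCTTCGGTTCAACGTATTACGAGAAAAGATCA
TCTGGAAGGCAGAGGGCCGGAAAAAGCAGAAATCGACGGAATACGATATAAGACAGGGGGCTAACTTCTA
CGAGTGGATG
>rnase_h
GAGTATTGGTTTATCCGCACCCATTTTCGTTTCATGCAAGCCAAAGACTGCGAATGCTATCAGATGCTGT
ATAACAGGTGGTTTTTACACGCAAACTGGGCAATTAACAATCAATACAATACAGCACCGGTTTGCAATAA
CTGTGTAATCGGCTGCTTTTGGTACTTTGGGAAGTGCTGGCATGACCAGGTCATGCTTATGGTGACCTAT
CGAGATCAACATTTCCATTCACAGAATTGG
>integrase
TTTAAGAAGAATTTTTACTTAGACTTCCGGGAAGAATTTAAGGGGTGTCGTGGAACGCACTATAAAATGA
TGTGGCACATCTGGGCTGAATTTTTGTCCATAAAGCAATGGTTCAAGAGCATGACAGTTAATTGTTCCGT
ATATGATAACACAAGTCATCTCCAGCGCCCCGGAAATGGTAGTTTCTTTCACGTAGTGCACTGTGACACT
GAGATGAGAAAATTTGTTCTGGAAGGGCATAACGACTTTACTAGGCTTTCACTACGAAAGCTCGAAGCCT
TCCCAATGGGCGCTGACTCT
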