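>HT1_synthetic
ATGACAGGACGGAAACCCCGAGAAAACAACCCATGATGCCCCGTTTCTAGCATTAGTCCGGACTTCCACCCCAGGTCGGT
CTGGATATATAGCTGAATCATTTAAAGCAAGGGACCTGTCCTGGTGACCAGGCGCATCTATGGTATCTAGCGGAACCCTT
AAACAGCGGCGGTAATCTCACGGGGGTATGATGTCTATGATCACCCGACGGGGCGAGTTACTCTCGTAATAGGAATCCTC
TTGCATGTACATGAAGTGATTAAAATAATCCCATAACCCTCCACTCCTCTAATTGTTACTAAGAGACCCTGAGAAAGAGC
ATTGGTTCTAGCTTATCGTAGGTCCAATTAACATATGCGAGCATTATCGGGGCTATCAAGCTGGGACAGTGATCAGGAAC
AAGCGTTAGAGGCATTCAAGCCTGAAGCAGGAGCATCCTTCTTACATAACCAGCTTGGGATTGTATATTACACTGAGAAG
TAGGGTCAACGTGCTGAGTTGGGAAGGATAAAAGGTATTCGTGGACACGCTCCAAAACAACTCAAT
>HT2_synthetic
ATGACAGGACGGAAACCCCGAGAAAACAACCCATGATGCCCCGTTTCTAGCATTAGTCCGGACTTCCACCCCAGGTCGGT
CTGGATATATAGCTGAATCATTTAAAGCAAGGGACCTGTCCTGGTGACCAGGCGCATCTATGGTATCTAGCGGAACCCTT
AAACAGCGGCGGTAATCTCACGGGGGTATGATGTCTATGATCACCCGACGGGGCGAGTTACTCTCGTAATAGGAATCCTC
TTGCATGTACATGAAGTGATTAAAATAATCCCATAACCCTCCACTCCTCTAATTGTTACTAAGAGACCCTGAGAAAGAGC
ATTGGTTCTAGCTTATCGTAGGCCCAATTAACATATGCGAGCATTATCGGGGCTATCAAGCTGGGACAGTGATCAGGAAC
AAGCGTTAGAGGCATTCAAGCCTGAAGCAGGAGCATCCTTCTTACATAACCAGCTTGGGATTGTATATTACACTGAGAAG
TAGGGTCAACGTGCTGAGTTGGGAAGGATAAAAGGTATTCGTGGACACGCTCCAAAACAACTCAAT
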