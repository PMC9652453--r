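AAAATTTGGCC
AAACCGCGCCG
AAAGGAGAGTG
AAATAGAAATT
AACCTGGATTA
AACGCTGAATA
AAGAGAAACAC
AAGCGCAGCCA
AAGTTCCTTGA
AATCCACTCGC
AATGTAGTGCG
ACAGAAGAGCC
ACAGATCCGCC
ACAGTCATTAG
ACCTATCATAA
ACGCAGTCTAG
ACGTCCGGTCC
ACTATATGAGG
ACTTGTCTAGG
AGAAAGCAGGC
AGCAAGCGCTG
AGCAGGCATAG
AGGTTTTGCAA
AGTCTCGCCCG
ATACCAGGTTA
ATAGGCCTTGA
ATGAGTGAACG
ATGATTCGTCC
ATGCTGGAACA
ATTACAACTCA
ATTTGTATGCT
CAACATATGGA
CAAGAGAACGA
CAAGGGCACTT
CACAGACACCC
CACCTGTTCAG
CATAACCAGCG
CCCCCAGTCTA
CCGCAAATCGT
CCTCCTCTTGG
CCTGGTTTTAG
CGCGCATTGCA
CGCGGAAGATA
CGCGGTTATGC
CGGTGATCGGC
CGTCGAAACAC
CTAATCGCTCC
CTCGCGATGAA
CTGAGGTACTG
CTTCAAACTGT
CTTGATTGTAT
GAAACAAGAGG
GACACCAAAGG
GACCTCAGTTG
GAGATTCGCGA
GAGGACCGGTC
GATCGCCGTAC
GCACTGGCAGG
GCATGGTTGAG
GCGGAACGGTA
GGAAAGTGTTT
GGAACAGTTGG
GGACCAGAAGG
GGAGTGTAACT
GGATAGGTTCT
GGTGAGGGGTT
GTAACGAGCCT
GTCAAAAACGC
GTCGGCAATAG
GTTTGACGTCT
TAACTCTCCGT
TAAGAAATACA
TACGGCGGTCA
TAGCCTTTCCG
TATAGGTCTTT
TCAAGATATCG
TCAATCAATGG
TCGCAGTGTTT
TCGTGAACCAG
TGACAGTAAGT
TGATCCCGCCA
TGCAGGGCAGC
TGCTGTGTAAA
TGTATTGAGAC
TGTCATAGGTT
TGTGTGGTCTT
TTAGACGTATA
TTCACCAACTG
TTCGGGAGTAA
TTTAGCAGGAA
TTTATAGTAAT
TTTATCCGAAA
TTTCAGCCAAA
TTTCCATCCTT
TTTGAACCAAG
TTTTACGGTGT
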