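>Alu#AluSx1
GTCCTGTACGATCAGGTACTCTTAACGCCTTACATTACGATTTAAACGTAATAAGTGTATTCACTCATCA
ATCACGCCGACTCGGGGTACCAACAACCTAGCGAGCCAGAAGGTTACTGGATTAATAACCGCACGTTGGA
TGCTACAGCCTTGCTTATTCCACAAGCCGCAGATCACGCATCCAAAAATGAGCATATCTTCTTCTTAAGA
AAAAGGTCGGCAAACGTTGTAAGTATGTTTAGTGGGTACTTTCTGGCTCCCTTACGTTGGGTCCACGCCC
TACGACTTTCAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>Alu#AluYa5
GTCCTGTACGTTCAGGTACTCTTAACGCCTTACATTACGATTTAAACGTAATAAGTGTATTCACTCATCA
ATCACGCCGACTCGGGGCACCAACAACCTAGCGAGCCAGAATGTTACTGGATTAATAACCGTACGTTGGA
TACTTCAGCCTTGCTTATTCCACAAGCCGCAGATCATGCATCCAAAAATGAGCATATCTTCTTCTTAAGT
AAAAGGTCGGCAAACGTTGTAAGTATGTTTAGTGGGTACTTTCTGGCTCCCTTACGTTGGGTCCACGCCC
TACGACTTTCAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>Alu#AluYb8
GTCCTGTACGATCAGGTACTCTTAACGCCTTACATTACGATTTAAACGTAATAAGTGTATTCACTCATCA
ATCACGCCGACTCGGGGTACCCACAACCTAGCGAGCCAGAATGTTACTGGATTAATAACCGTACGTTGGA
TACTACAGCCTTGCTTATTCCACAAGCCGCAGATCACGCATCCAAAGATGAGCATATCTTCTTCTTAAGT
AAAAGGTCGGCAAACATTGTAAGTATGTTTAGTGGGTACTTTCTGGCTCCCTTACGTAGGGTCCACGCCC
TACGACTTTCAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>L1#L1HS
TTGGGGTCTCAGCAGTAAGCCTGTCTAGGCGAATAACTGGGTCCCGAGCGAGTGTGGTAATGCGTTATGG
CTCCCTAAATATCGGAGACACGCCCTTTATTCGGAGTGTCTTTGGTGTTTAAAGAACGTGATGCGTTATG
CCACCATTCAGTATCGAATCAGCTCGCAAGATTGTTATGGGGCCATTAAGCTCGCTGAATTCACGTCGCC
GTATCGGTCGTTGAGCCGCTTATTCCGGTTGGCCGCCCAGTAAAATCAAACCCTGCTAGTCAGCCGGATG
CTGATACTCACTAAGCAAGCTTACATCCGGTAGTACCACAAACGCTGCGCGTTTCCCTGCCTATAATGCT
GGCGCAAGGGATCTCGGTGGACAAATTAGGTGGCGAGACGACCCCAGGTAGTGCGTCGCGCGACACTACG
TCAACGATGTCTCCCCGCAAAATTTGAGACGAACAGTCATGAGAATAGGGGATGACACATTACATCATGG
TGAATACCGGTGCACCTTAGGGCGCTATTATCAAAGCATTTTATAACAATGGCGCAATTTACGTGATGTC
CGTCGAATCTTTAGTACGGTCCCTCTTGGTGGGCTTACCGCTAAATGGGTCAGCCGCGAGTCATGATCCC
TATGGATCTCAGCTCTCGCCCCCTAATAGACCTATAATCAAACAACATGAGCCCTACCGTGCCTCTCGTC
TGCCGAAGCAACCTACGGGAGAAGAATAGGAGGAGCTACCAGATGTGTACACCGCTCCTCGGCTCTTTAC
ATTAACTCCTTAGGAACCGCCACACATCGAAACGGTGGTTCAATCCTCCCGAACTAAACCTCACATGCTT
TTTGACAAATGAATGCTCGGCTTTCTTACGTAGTTTCCCTCGTTTCCTGGATTCGATCACGGGGTACACG
AGTCAGCCACCCGGGAACACCTGCGGGCGACCTGTTCTCAATGTCATTACACGCATAACGAGGTGTCACA
CCAGAAGAGTGCATTAGCCCAGCAGTAGAGTCCGTCTCTATGACCTATCCTGGTCACATGCTTCCTGCTT
AACTCAAGAGTATCTTAAAGTTTGGATGAATCGCTAAATCGTCATACATAGCTTACGCACGGCATAAAGG
CCGAGTCAGTGCCACTGCGTGCTGGCGAACGGCAGCGATGCCACACTGCCCAGCCAAGCACTCCGAATAT
GAGACCGCTGTTAGGCTTATCCACGCCTACACGCGTATCCTCGTAGAGCGGCTCAGTCGTATGCATCTTA
ATTCACGGCCAAAGAGCTGGGCTTGCTCCCGATACTTATATCCGGTTTACCTATATCTTAGGGAGCACTG
TAGAATCAGTACCTCCCACCCGCCTAACAGACCCAATGACTCTTATTCTGTATCTATCTAGGCCGTACTC
GATAAACAACTCTAACATGAGAAGGATGGAGATCCGCTCGGATAACGGCCTTGCTGCAAGTTGAGACGGA
GGTCGTTACCGATAAATCCTTGACGCAGGGACTAGGACAAGCTGGAAGGACCCGGAATCCGGCCAACAGA
ACGTGGGGCAATGACTTTAGGTATCTCGTATTAATCGAGCAGTGTATATTTTTCCGTCACGCCCCCCTGC
CTGGAGAGTCTATTCGCTGTTGTGATAATACTACGGCATACGATGACGCCTAGCCATGCGTGCTGCTTTA
GCGTGTAAACGGCTTTGTCGTCCCTAGCGCCCAGTCGCTCTTCTGGATATACGGTTCGGTACGTCTGCCA
ACAATCGCGATGCGATCGATCGGAGTAACTCACAGCTCAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>L1#L1PA2
TTGGGGTCTCAGCAGTAAGCCTGTCTAGGCGAATAACTGGGTCCCGAGCGAGTGTGGTAATGCGTTATGG
CTCCCTAAATATCGGAGACACGCCCTTTATTCGGAGTGTCTTTGGTGTTTAAAGAACGTGATGAGTTATG
CCACCATTCAGTATCGAATCAGCTCGCAAGATTGTTATGGGGCCATTAAGCTCGCTGAATTCACGTCGCC
GTATCGGTCGTTGAGCCGCTTATTCCGGTTGGCCGCCCAGTAAAATCAAACCCTGCTAGTCAGCCGGATG
CTGATACTCACTAAGCAAGCTTACATCCGGTAGTACCACAAACGCTGCGCGTTTCCCTGCCTATAATGCT
GGCGCAAGGGATCTCGGTGGACAAATTAGGTGGCGAGACGAACCCAGGTAGTGCGTCGCGCGACACTACG
TCAACGATGTCTCCCCGCAAAATTTGGGACGAACAGTCATGAGGATAGGGGATGACACATTACATCATGG
TGAATACCGGTGCACCTTAGGGCGCTATTATCAAAGCATTTTATAACAATGGCGCAATTTACGTGATGTC
CGTCGAATCTTTAGTACGGTCCCTCTTGGTGGGCTTACCGCTAAATGGGTCAGCCGCGAGTCATGATCCC
TATAGATCTCAGCTCTCGCCCCCTAATAGACCTATAATCAAACAACATGAGCCCTACCGTGCCTCTCGTC
TGCCGAAGCAACCTACGGGAGAAGAATAGGAGGAGCTACCAGATGTGTACACCGCTCCTCGGCTCTTTAC
ACTAACTCCTTAGGAACCGCCACACATCGAAACGGTGGTTCAATCCTCCCGAACTAAACCTCACATGCTT
TTTGACAAATGAATGCTCGGCTTTCTTACGTAGTTTCCCTCGTTTCCTGGATTCGATCACGGGGTACACG
AGTCAGCCACCCGGGAACACCTGCGGGCGACCTGTTCTCAATGTCATTACACGCATAACGAGGTGTCACA
CCAGAAGAGTGCATTAGCCCAGCAGTAGAGTCCGTCTCTATGACCTATCCTGGTCACATGCTTCCTGCTT
AACTCAAGAGTATCTTAAAGTTTGGATGAATCGCTAAATCGTCATACATAGCTTACGCACGGCATAAAGG
CCGAGTCAGTGCCACTGCGTGCTGGCGAACGGCAGCGATGCCACACTGCCCAGCCAAGCACTCCGAATAT
GAGACCGCTGTTAGGCTTATCCACGCCTACACGCGTATCCTCGTAGAGCGGCTCAGTCGTATGCATCTTA
ATTCACGGCCAAAGAGCTGGGCTTGCTCCTGATACTTATATCCGGTTTACCTATATCTTAGGGAGCACTG
TAGAATCAGTACCTCCCACCCGCCGAACAGACCCAATGACTCTTATTCTGTATCTATCTAGGCCGTACTC
GATAAACAACTCTAGCATGAGAAGGATGGAGATCCGCTCGGATAACGGCCTAGCTGCAAGTTGAGACGGA
GGTCGTTACCGATAAATCCTTGACGCAGGGACTAGGACAAGCTGGAAGGACCCGGAATCCGGCCAACAGA
ACGTGGGGCAATGACTTTAGGTATCTCGTACTAATCGAGCAGTGTATATTTTTCCGTCACGCCCCCCTGC
TTGGAGAGTCTATTCGCTGTTGTGATAATACTACGGCATACGATGACGCCTAGCCATGCGTGCTGCTTTA
GCGTGTAAACGGCTTTGTCGTCCCTAGCGCCCAGTCGCTCTTCTGGATATACGGTTCGGTACGTCTGCCA
ACAATCGCGATGCGATCGATCGGAGTAACTCACAGCTCAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>SVA#SVA_E
CTACATTACAAACTTTGACGAGATGGATTGCAACACCTCAACGTTCTCCACGCTACGCGTAGGATCAGGT
GTGAGGAGTTCCAGTTTAACATTCCAGACTCAACATAAGCTATAAAACCTCCGCAACAATTACCTACGAG
AGACCCCGCCATGGGCACACAATTTTGGTCTTCTATCGGAGGGTTCAAGTATGATCCGCGATTGACGGGA
GGTGAGAGGTGGTGCCTCTCGCTATTTCCTTACTTATCCCATTTTCTGTATGTGCCCGAACCTATGCGAC
AAGCCACGTGGATTATCAAACGCATCCCCTTGAAAATTCAAGACGGGGAGGATGTAAAAAAGAGGGAACG
TTAACTCTTAGGTTGACTAGCTTAGCACTACATTTTCGCCAACATTAAAAGGGCCCAATCGTAGCTACCC
CGTCAACGATAGGCCTGACGCCTGGATTATTACGGCTAGGGCGTTCCCGTCCGTAGTCGAGACTCCTTGT
ATAGGTAGGCCTGCTAGCAAAGCTGGCCTAATTGTGGTTAAGCGTCGCACCCGGACGGCTCCAGCGCCCA
GAACCACATAGATCCATCAAGTAAACTATTCGCTGTTGGGAGATTGACTCACACGGTAATGATTTTGGTG
GACATCTCCGATGTAGCCGCCCAGCGGGATCCAGTTGTCATAGTGTAGTACGGCTCGGCGAGTGAACCAA
CTGATGACGATGGAGGCGTCGAATATCCTTCCGCAACTCTGCTGACCAAGTCGTTTGGATACGAATAGCA
TATTTGCCAATCTAGAGTAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>SVA#SVA_F
CTACATTACAAACTTTGACGAGATGGATTGCAACACCTCAACGTTCTCCACGCTACGCGTAGGATCAGGT
GTGAGGAGTTCCAGTTTAACATTCCAGACTCAACATAAGCTATAAAACCTCCGCAACAATTACCTACGAG
AGACCCCGCCATGGGCACTCAATTTTGGTCTTCTATCGGAGGGTTCAAGTATGATCCGCGATTGACGAGA
GGTGGGAGGTGGTGCCTCTCGCTATTTCCTTACTTATCCCATTTTGTGTATGTGCCCGAACCTATGCGAC
AAGCCACGTGGATTACCAAACGCATCCCATTGAAAATTCAAGACGGGGAGGATGTAAAAAAGAGGGGACG
TTAACTCTTAGGTTGACTAGCTTAGCACTACATTTTCGCCAACATTAAAAGGGCCCAATCGTAGCTACCC
CGTCAACGATAGGCCTGACGCCTGGATTATTACGGCTAGGGCGTTCCCGTCCGTAGTCGAGACTCCTTGT
ATAGGTAGGCCTGCTAGCAAAGCTGGCCTAATTGTGGTTAAGCGTCGCACCCGGACGGCTCCAGCGCCCA
GAACCACATAGATCCATCAAGTAAACTATTCGCTGTTGGGAGATTGACTCACACGGTAATGATTTTGGGG
GACATCTCCGATGTAGCCGCTCAGCGGGATCCAGTTGTCATAGTGTAGTACGGCTCGGCGAGTGAACCAA
CTGATGACGATGGAGGCGTCGAATATCCTTCCGCAACTCTGCTGACCAAGTCGTTTGGATACGAATAACA
TATTTGCCAATCTAGAGTAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>LTR#HERVK
CACGTGGAAACTTGGGGTACCGTAGGATCGAGTCAGAGCGCGGTTCCTGCTCAATGAAACATACCTCTAA
CTCAATAGGCTTACCGGTGTAGTAGATCGGCTTGCTGTCCACTCCTTGAATGGTGCAGACTGGCTATGAA
TCTTATGGATATCACATACAAGAAACGCGGCAGCGTCCTCTACTGATAGTTAAAGCTTGGAGCAGAGGTA
TGCGATTCGGCTTGGAACTCTTCGACGGCTCCGGGAATGTATAACCTGCCGAGAACGATGCCGGTTCACA
CGAATTGTACAGAATAATCGCGTACACTGTGTGTGACACACTCTTTCCGATTTAAATCTACGTTACTGTG
GGATTTCACCTTCCTGGCGCAGTGGTCATATGGGAAACCCTGTACTGAACTCGTGTGCCGTGCCAGCTGC
CGATTGGGCAGTAAGATGGTCGGCGAGCCTGCTCTAATTGAAGTTGCGCCCTATACTTAGTGGCCCCTTT
CACCTCTAGA
>LTR#HERVH
CACGTGGAAACTTGGGGTACCGTAGGATCGAGTCAGAGCGCGGTTCCTGCTCAATGAAACATACCTCTAA
CTCAATAGGCTTACCGGTGTAGTAGATCGGCTTGCTGTCCACTCCTTGAATGGTGCAGGCTGGCTATGAA
TCTTATGGATATCACATACAAGAAACGCGGCAGCGTCCTCTACTGATAGTTAAAGCTTGGAACAGAGGTA
TGCGATTCGGCTTGGACCTCTTCGACGGCTTCGGGAATGTATAACCTGCCGAGAACGATGCCGGTTCACA
CGAAGTGTGCAGAATAATCGCGTACACTGTGTGTGACACACTCTTTCCTATTTAAAACTACGTTACTGTG
GGATTTCACCTTCCTGCCGCAGTGGTCATATGGGAAACCCTGTACTGAACTCGTGTGCCGTGCCAGCTGC
CGATTGGGCAGTAAGATGGTCGGCGAGCCTGCTCTAATTGAAGTTGCGCCCTATACTTAGTGGCCCCTTT
CACGTCTAGA
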