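>IGHV1-2
TGTACACGGAAAACGTTTAGCCTGTTATACCTTCCTGAGGCCGCCATGAGTAATTGTGAGAAAA
>IGHV1-18
AATTCGTCGACGATGGGCGTGAACGAGCCCCCGGCAGGAATGAGGCATCCCCTCTGTCTAGCATTA
>IGHV1-24
CGTGGTGCAATTCGGCCTATGGCACGCCAGTTACAATTGTACTCCTTAAGGAAATGTGTCGGTCT
>IGHV1-46
CGGATAGACGCGGTAGGGGGCGATGGCAGCAATCCCCGGGTCGTAGTTTCCGTCTGTTTAAAGCAA
>IGHV1-69
CGGAGCACCAGTACTTGCGATCTGTTCATGCAGCGGGTTCCTGTCACGGGAAAATGTGCGCATCT
>IGHV2-5
TCTCTACGGCGCTCTCTCTCCGGGGAGACCTGCCCGCTGAAAGTCTTATCCGCATGTTAAACAGCG
>IGHV2-26
TCAAATCCGCCTGTGTATTGGGTTACTGGTAGTTATACTCGTCATATCTCACATTGTATGATGTCT
>IGHV2-70
AAAGTGCGGTGGGTTATTGTATGCACGCAAACCGACACGATAAAGCCGCCGAATTGTAGTTACTC
>IGHV3-7
CGCGGAAACGCTTCGTGTCAGTCGCGGAAGTCGGTCCTATTAGTTAGGGCTCACTGTCATGTACATGAA
>IGHV3-9
ATCGTGAAGTCTAGAGCGTATTGGGTCGCCAAATCTCCCATGAATATGTGTCGCTGTACCCTCCACT
>IGHV3-11
TTAGCGTGCGGGTCTTCGAGAGGTTCAGCTGCGTATATGGCGTGTCGAATCTGGTGTACCCTGAGAAAG
>IGHV3-15
GGCAAGAATTCGCTCCGGCTCGCTCCCGTCATGGTTGGGAAACTCTTAAAGCTATGTTTCCCAATTA
>IGHV3-21
TCTTCCGGCCGCTCGGTGAACTTACATGACCATTACGAGCAGAGATCTGGTATGTGTGGGCTATCAAGC
>IGHV3-23
GCTCTTGAACATAGGTGGAACCTCCGTCCACTCTTATCGCTGCTGGACAAATGCTGTAGCGTTAGAG
>IGHV3-30
AGGTTTGCTCACACGGTCTTGCCGGGAGCAGTTCGGTATGAGAGCGAGCCGATATGTGCATCCTTCT
>IGHV3-33
GGTGGCAGGGACCGCCGATTGAATTTCCGAATATCCCAGGGGGAACCTACCGAGTGTGTATATTAC
>IGHV3-48
CCAATGGTGCCGTGTAGCGTCTCTCCGGCGCGACGTCCGCCGCCCTCCTGTTGGTGTGTGCTGAGTTG
>IGHV3-53
CCTCGTGACTCGCCTCGTTTTGCTGGCCGAGCCGCCAACCCTGTTTCGCGCTTATGTTGGCCACGCTCC
>IGHV4-4
GCCAAAGACGTATCTTTGTGCGGGCAATGGTGTAGAGGTGGCAAGCCCAATATTTGTACTTGTGAC
>IGHV4-31
AAAGTTCCAATTGGCTCGCAGGGGGTAGGCACAATGAGGCTTACTCCAGCTAAATGTCATAGTGTTAG
>IGHV4-34
AATAGGATAAGAAGCTTTCCCCCTCCACAATCTCCACTAGAATGCACTTTAGTATGTGGTCCCATGTGA
>IGHV4-39
CTGCGAAGATCCTTGGCACCTGATATCGTGTTCGGATTCAAAGCAGACGTTGTATGTCCTGTTAGCGT
>IGHV4-59
CTCCTCCTACCGACACATAATTGCGTAGAAAATAACTTTACGAGGCCTTTTGATTGTTTCAACGTC
>IGHV5-51
TCGCGCGCCGAATGCAGCGCGCGTTATTCCCATGAAGATGATGGTACAGCGATTTGTAAGACAAGG
>IGHV6-1
ATTGTGGCTATAGCAGATGCGTGTGCACCCGGGAGTGAGGGGATAATAAGTGCCTGTATACCGGTTG
>IGHV7-4
GCATGTATACCTATTTCGGGCCAACGGATTCAGATGGGGCTTTCCCCGATAGTATGTCTCGGCAA
>IGHD1-1
TCACAAAGCACAGACAAGCTTAA
>IGHD1-7
ACACTGATTAGTTAGAGAAA
>IGHD1-26
CTTTACTTCGTCGTCCCGCCATTG
>IGHD2-2
TCGATAGTGCAACTA
>IGHD2-8
TCGCAGAGACGTGCATT
>IGHD2-15
AATTCATGCCGGGGA
>IGHD2-21
TTACCTGTTATT
>IGHD3-3
CTGATTTACATCGATCA
>IGHD3-9
AAGTAGCAGCCTC
>IGHD3-10
CGTACGCAACACTACCGC
>IGHD3-22
GTCCTGAATCCTTTCAACCTATGT
>IGHD4-17
CGAGGTAAAAGAGCGG
>IGHD4-23
TTGGAGTTACATCCCCCGCGTC
>IGHD5-12
ACGCGATGCAACAACACT
>IGHD6-13
CTAATCAACAGTTGTGACTCT
>IGHD6-19
AGGCACAATGACTCCCTTC
>IGHD7-27
AGGAAACTCAATGTCCGCCAG
>IGHJ1
CTTAGGATTAGCATGACTTGGGGGATATTTCACCACGTTCACGG
>IGHJ2
CGCCTGGTGGCTGGGGTCAGGCATGACCATTCCGGGC
>IGHJ3
ATACCGCAGTCTTTATGGGGTCCCAGAGCCGCCTACTCAGA
>IGHJ4
TTGCGTGTAATGGGGAGCGCAAGAAGCGTATTCCTT
>IGHJ5
CCGGTATTCGGCGCAATGGGGCTACTTCGCGTATCAATCTCC
>IGHJ6
CCTATATAAGGTCTATGGGGTGTCGTCTATATACTGCTATC
>IGKV1-5
TCGCGTGGAGCCTTTGCGAGCCTCCAGGGCCGCCTTCTAATTATTCCAAAGGACTGTCAGCGAAACTT
>IGKV1-9
ATGGCGACTGGCACACGACGACTGTGTCGGGCGATTACCACACCGCGTGTCGGTTGTATTCCCAT
>IGKV1-33
AAAGTGCCGACCCGCATAACTAGCACTCAACGGCCCTTAGGTGATGGAGCCGAGTGTTTTTGTACCATT
>IGKV1-39
GGATTGAGCCGAGGTGAGTTGCGTATACCCCCCCGTACGCGACATGTACCAGAATGTTCAACTT
>IGKV2-28
ACCGGTTACCAAAATTCCGCGCGTGATACATTATTTATATTGCACGGCCTTGCGTGTGGTGCACTCG
>IGKV2-30
CCCGCACCAACCCCTTACACGTATGCCCGGCCCTGCCAGCGGGGGGGAATAGCCTGTAGTACCGA
>IGKV3-11
GTCGACAGAAGGTGTCAGCGCGCAAGCGGAATAGGATTACTGCACAATATCTGGTGTTGACGG
>IGKV3-15
CAGCACGGGCCCACACGTCGATGTCACTATAAGGGAGAGGGGGACGTATTGGGCTGTTATCCAA
>IGKV3-20
GTGGATACATGCTCTAGGTACCCGTATAAAGCCGTTGATTTATTCAAAAGCATTTGTGAGCGGCCTACT
>IGKV4-1
CCCCGTCATAAATATTCATTTCTCCGCTGCCGTAGTTCTTTCTCGCGCGGTCTCTGTCGAGTGAC
>IGKV5-2
CCGCGTGGCCGATTAACCTTTCGTGGTTGCGGGCACAAGGTATGGCATCCTGAATGTCGGGCGTG
>IGKV6-21
CTTGTAATAAGACCAGTCGTCTTTGAGTTTATCTATTCCGATGAGGATGCGACGTGTTATTTG
>IGKV7-3
AGTCCGTGTGTTGTCTCTCGACTTCCAGGTCTGCATCCACGCATAGGAGCCGCCTGTCGACATAAA
>IGKJ1
CGATGTCGTACATTTGGATCGCTCATCTAAACCGTAGC
>IGKJ2
CAGTATCATCTCTGGTTTGGATGTCCTACACACACCGGAGG
>IGKJ3
ACCAAGCGGAGTTTTGGAGCAGTTCCGTCATAAAGCAA
>IGKJ4
CCGGAGCTGTACTAATTTGGCTCAATTCGCCTTCAAACAAG
>IGKJ5
AACACTAGAAAGTCGGTCTTTGGATGCGGGTAGAGCTAGCTCGG
>IGLV1-40
GGTGGCTTCGCAGTTTCCAGGTATCAAGAGCCAGAGGAAGCAGCGGCCTTGCCCTGTGGATTTGAA
>IGLV1-44
CAGAAATACTGGTGTCGCATACAAATAATAAATGAGGTGCAGCCGCAATCATGCTGTAGGGGTTCG
>IGLV1-47
CAATTCCCATCTTTGTCGGGGGCACGTTGTGGTACTTCTCCTCATTACATGGTCTGTTTTTCG
>IGLV1-51
CTAATTATTAAGCCCTGGTCCCGAAGGGAATCCGTGATTCTTATTACTGAATATTGTCCGTTTACT
>IGLV2-8
GGGATAGTTGGTTCCCATACAATCGGGCCCACTAGAGTAGTGCGACGACATTCCTGTGAGCCAAAGGG
>IGLV2-11
GTGGGCACGCCTCACGCTGTACGCGCTTTGGCAACTCCGATCCACTCCCTGTACTGTCTGCTTGT
>IGLV2-14
AAGGAGGATATGTGCTTCACAGGAGTTCGTATCCATCGTTTGTCAAATGGATGTTGTGAATAGCT
>IGLV2-23
GGTGTAGCCCAGTCGGGGATTGCATGCTATCCCAGCATGAACTGTGGGATAGAATGTACACGC
>IGLV3-1
GGTCGGCCAACACATCAAGGCAAGCGGAGAGAGGGGTGGCTGAACAGATATACTTGTTTGCCACG
>IGLV3-19
CTCCGGTGGCATCATTGGTGCCATATCCATAACCCGTACTTCACAGCCGGGAGCTGTATCGGACGT
>IGLV3-21
ATGACCATCCTGATTATAGAATTCAACACACTAACTCGAACCGCCACGTGCTGGTGTCCCCCAT
>IGLV3-25
CAAAATACAGATCATAGACGTCGCGAACTGTACCTTATGATATTCTACACAGTTTGTATGATAATC
>IGLV4-69
CTTTGCACATCCGTCTTAAGGGATGCCTACATTCTTGGCACGCAGGGCCCAACTTGTTACCCCAGAC
>IGLV5-45
ATGGCCGTCCGCAATGCTGGGACGCTCCAGACCCGCTTGCTGTCTCGAACGTGGTGTTTCTGCAA
>IGLV6-57
GTGTCAACGTTGATACGGCCATTTTGGATGGAAATACTTTTTCAATGGCACGACTGTCAACCCGCCC
>IGLV7-43
GGGTTGACAGAAAGTGTGCCGAAGAGCCCGTTGTGCGCTGGCTGGCCGGACTGCTGTCCATGTTGCC
>IGLV7-46
TGGGGTGAAGATACCCACAGGGGGACCTCGAATTTGGTTCGAGTAAGACTAGCTTGTTATACCAGAA
>IGLV8-61
GCCAGTCCCCGATGCCAGCACTCATGTGTATGCGATTTTATTTGTAGCCCGCAATGTCCATCAGGGGC
>IGLJ1
TTGGTGACCATTTGGCAAAATACACTCGGATCGACA
>IGLJ2
TTAGCGCTCTCTGCTTATTTGGTCTAAGTCGGTACTATACCTA
>IGLJ3
TCGTCCCGCCTTGAATTTGGCACTGGTTAATATGTAATAAC
>IGLJ7
CGTTGCTAAAGCCCGGGTTTGGGTGCTAAAGGAAATTAACACC
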