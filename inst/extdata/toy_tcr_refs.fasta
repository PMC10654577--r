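>TRAV1 locus=TRA role=V cys_offset=245
AAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCACGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGCAACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCTCCCGCTTGCCGTCTTCAACTTCATGACCCTCGTGCATCACAAAGCCTCAAGCCGGAGTCTAGGCTTTGT
>TRAV1-UTR locus=TRA role=UTR utr_of=TRAV1
GAAACAGCTGAATAAATCGTGTGAATACGTGAGTCGTCGGAAAGCAGTTGAATATCTAACGACCCCTGCGCAAGGACACACTAGTCGCCCTTGAGAGCACTCCAGTCCAGGCGAGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGGTTTATCTATGCAGCTAATATCCTTAGTAGTCGACCCCTGAGATGACCGGTCATCAGGCGGCATCCGACGCACCAACGGCTCCTACAGACTCGTGCTACCGGACCATGCGACTCGAA
>TRAV2 locus=TRA role=V cys_offset=206
ATCAGATGGACAGACCTCGTAATAGCCGGGCCATGTAACACTGATGTCTCCGGGCAGCTCATGACGAGCACCAGACCCGAGAGTTCCTGTTAGTTTTGGTTAGGCACGGAACGCTATCGAGCGCGTAAGCGCCAACCCGCATTTACGAAGTACCCATCGTATGTAATAAGACCTCGAGTACGTCGGGACGTTGGCTGTGATGTTTTTGT
>TRAV2-UTR locus=TRA role=UTR utr_of=TRAV2
ATGAGCGAAGTTCGACGTTGCCGATGTTTACCCTAAGGGAGACGACATCATCGCACGACTCGTCATTTGCATCATCTCCACTGCCCCGATGTCTGCTATGGACGGCTTCACCTGATGTGGAGCGAGGGTACTGATAGATATACGACAATGCACGTAGTCTCGATACGTCATTGGTACGAACAGTTCGTATTCCCCATGTCTGGACCGACGTTAAGCTCATGTCTCAGGACGGAGAATGCAGCCCAACAGCTT
>TRAV3 locus=TRA role=V cys_offset=275
GCCGGATCAAGCAGGATGAGAGGCACTTACTTTCCCCGCTACGATGCTTTGCACAAATTCTACCGCATTGATCGTGGATTACTAGTTTTGATGGCATGGGTAATGGTGGAGCCAAACATCCAGCTAGCAGCTGCAAGCTTTGCCTACGTGGAGTCTCTGTGAAATTCAGAGATACGCAGCTAATGGCCCCGCTTAACGGGTGCATCGGCACAGCCTCGTGCAGCCCTCACAAATTTCCGCCATCAGTGATTCAGTATTGTTTCACCGCAGTTACCTGT
>TRAV3-UTR locus=TRA role=UTR utr_of=TRAV3
TGAAGTGCCGCCATATACACAGGTTCATGCTAGAGAAACTGCCACCCGGGCTTGCCAACCGGCAACGTGGCGTTGATTGACAGAGCTTCTTAAGCCGCTGATGTCCAAAAACTGAGTTAGTTCGAGATAGTTGGATGTCGCACTAGAGGGAACAGCCATAGGACCGATACAGACAGTTCAATGGCGGATGCCCGCACCTGTATACACCTAGTATGTAAAAATTGAATACGAGAGGGGCACCCTTTTGCCCTCCCACTGTCTATTCCAGGTCGCCGAATATGTCCCGAC
>TRAV4 locus=TRA role=V cys_offset=244
TCGACCCGTTTGGTAGGCCAGGGGCCTGGGCTAAACACGGCCTTCCCGATTGCCATGAACTCGTTTCGCCTTAAAGTCCAACCGTAAAGAAGCGACAGCGACCTAATCCGAGCTTTATCTTTTAAGCGGGCGCGGGGATGGAGTCTAAGGCACAGACGGATGCTCATCATATCTCGTAGCATTCATAATGTTGTGAAAAACGGATAGGCTGGGTCAACAGATATGTGTGGTAGAATTACCGGCATGT
>TRAV4-UTR locus=TRA role=UTR utr_of=TRAV4
TCTTTTGCCGGTGGGTGCCCGGCGACCCGAAACTCGGATATGCATGGGGGAGGGCCACCCATTTATGTGCGAGCTGGAAGACGGTTCAGCGGTCCCTCTTTGGATCGATTCCAAATGACTAACTACGAGACGTGAGGCGTATAGAAACTTAGCGCCGTAGCAGAGGAATCAGGAGAGGCTGGTAAAACTAAGTGTGAAGTATAAAATGCGGCGCAGTTTGGTAGACTCATAGTATAGGACGCATACTCTGAAGTTCGAAGCGGTTCCTTTTTGCT
>TRAJ1 locus=TRA role=J motif_offset=0
TTTGGATTAACCAACAAGCCACGAGAGTTGTCCTCGTGTTTCGCAGGGTA
>TRAJ2 locus=TRA role=J motif_offset=0
TTTGGATGGACATTTGCGGCCGCCGCTCATGCTCGATATGAATAAGTTCA
>TRAJ3 locus=TRA role=J motif_offset=0
TTTGGTGGGATACCATCGATCAGGGAATCCCTAGGCCAGCGGATATCACA
>TRAC1 locus=TRA role=C
ATCCCTGTGGCACGGCATGGTGGGCTCCCCTTATCTTAGGTTTAGTAGCACGCTGATCCGCTCGATGAGCAAAAGACCGACGCAGTCCGCGCTTCATGCAGCTAAGTTATTATTAATCTTTCTCCAGGTTGGCTACGCTACCGTTCGGCA
>TRAC2 locus=TRA role=C
AACATATTGCTGCAAGATACTATTAGGTGGCTGGACTTGGGCTAGTGGCCGACTGCTAAGTATTCCCGTTTCAGTATACTGACACGTGAATCCACCAGGGAAAACCTTAGTAGCGGCCCGGTATAGCCAGCATAGGGTAGTAAGGGAGGC
>TRBV1 locus=TRB role=V cys_offset=286
ATCAACGATCGTGCGGTGTGGAATCCCAGAGAGGGTAGGAGGCTAAAGCTGTTGAGGGTAGGACTGACAGTGTGAGCGCGAAGGTCGTGTCTTCGTTAGGCTGACGCACTATACCACGTCATACGCTATCATGAATCTTCCTTGCTGTTGGGCTAAGCGGGGATCGCTTACGAGGTTAAATCCCGCTCTTACAGGGAAGAGAGAGTCTTCCTTACTCGAGACCCATAGTACTATGATTTCGGGCAAAGAAGACGGGACCACTAATATTTGACGGCTCCAATCTCATTGT
>TRBV1-UTR locus=TRB role=UTR utr_of=TRBV1
ATCGTCCGGGGCATGCAGCCCTACATCGTCCCAGCCCGGCTAGTAACGGTAGATTATCGATGTAGCGTCAAGGCCACCCATCGCTTGACGTAACAGGCCTCGTTCAAAGCCGAATCAACTTGGAAGTCTCACAGGTTCATGCTGCAGGCTGGGTGCCGCTTACACACGCTAAGACAAAGACTTGCGCCAAAACGCTGGTGCTAAAAGAGCTTGTGATGCGTACGAGGCCGCGCAAATTTCAGTTAGACACGATGACCACGAAATACCGGGGAGGTTTAGCTTGTTTGC
>TRBV2 locus=TRB role=V cys_offset=268
TAATCCCGCCAAGTAAATAGCCCAGTCGGACGCGGCTTCCGCTAGATAACCGAACTATTCAACCTATCCAAATGTGGCCTAAAAGCTTGATTCTCAAGTTTCCTATTAGTCAGTCATTTGGTGAACCACCGTGGAGGCGCATATTAAGAGTATACTATCGAGGAATTGCTGGATGGATACTATATTTCCAAAACAGCACTGTATTTGACGCCGCTATGGCCCTCGTGGGTGACATGCTGGGTTAGCTAGCCGGGCAACAACTCTTAGCTGT
>TRBV2-UTR locus=TRB role=UTR utr_of=TRBV2
TGAGTCGGGCTCAGAGTTGCACCCGTTGGCTGGGTTAAATATATCACACGGCAAGCGATGCGTCATGTAATAGGTGCGGAACTCCAGATTGGCGATGTGCAATTACTGTGCGACTTGTCATATCTACAGGGGACTCCAGAATATCACGTACTTCCCAATACCCAATATCTTGCAACCAAGCGTTTAATCACCTGTTAAATTGTGTAGAGTAGTAAGCAGATTACTGCGGAGAGAGAGCGCGAATCTATACTACGCTCCGTCTGGTTACC
>TRBV3 locus=TRB role=V cys_offset=267
TTGCCTGGTAAGAATGACTACGGCCTAGAATGGGTCCACACCCTGCCTCCTAAAATTGCACTGAGCAGCAGAGCAACGAGTGACAAAGCTGGGAGCCCCCAATAGAAAGTACTGGATTTCTATGCCACATGGGACCGGCCAATACATCATTCTGGAATGTTCCAATGTTGCTTCGGGATCATCTATCTTGGGCGGATAACATACGGGTACGTGCCTTGGCCGTCCTGCTCACGTGCTCGACGCTTACCGACATAGCTAAGACGTGCGTGT
>TRBV3-UTR locus=TRB role=UTR utr_of=TRBV3
TGAGGTTACTACGTCTGAAATTCCCCAGCGTTAACAATTAAGACCGTTATGCCACTAGTGTAGCTTACTGATAATGACAGGTACTAAAAAGTGCAATACCATCACGATCTATCATAGGTGTCATTGTAAAATCACGTCTATAAGACCTTTTCTGCTCTTGTACGGGTGCGATTAATACGTCTTCGGCTTAAAACCGCATCACAGCGTTGTTCTCCAAGATACAGAAGGTACCCTTCACTATTAATATAGAGTCTGATTCCCAAGGTAATTAAACACTTCTGAGACTTGTAGACAATGCA
>TRBV4 locus=TRB role=V cys_offset=260
GCCTCACCTAGCATCGGTTGTCCGCAACAAGAGGCTTCTTGCATATGAAGAGTCTTCTCAGCACTTGTGTTTACTGTTAGGCTGTCCGTATAAAGCTGCGCTAGGTCGAGCTCTCGTCCTTCCAGGCAGTACCAGTGTCGTGCGTGCCCCCGTGGTCGGATTAACTCACCCTTATCAAACTGGCCCATCTCAGGTTCGCGCTTACCGACAACCGCCACAGTCTTACCAGCATCAGGATGACGGCCTGTGTGGACTCGTGTTGT
>TRBV4-UTR locus=TRB role=UTR utr_of=TRBV4
ATCGACATTTCTGACAGGAGTACTGGTTCGTATTCCCGTATATCACACGCGAGCGAAACGGGCTGCGGTGTATATTAGAGCACTTATGAAAAGACCGGAGTCTATATTGTCATGGACCGTGGAAATATGCTCCCTGCCGGTGGTGCGTCGGCGAAGCCAGTTTGCGAGACATGCATCTGGTACTAGTGAACTGTGAGCTTAGTTCTCGAGTCCCAACGAAGGACTTCGAGCCAATCCTCTCACTGGTGTACTGATTTCTTTAAGATACGTTGCCACCTT
>TRBJ1 locus=TRB role=J motif_offset=0
TTCGGCGTTCTGGTCGCTGTCGTAGCTTGGTCTAAACGGGAATTCTATAT
>TRBJ2 locus=TRB role=J motif_offset=0
TTTGGCTCCTAGACGTGTCATATTCGCTCTTTCATATTGAAGCTCATCCT
>TRBJ3 locus=TRB role=J motif_offset=0
TTTGGGTATTCCCTCCACCTTATGTTCATGTAATTCTAAACCGGAGACCG
>TRBC1 locus=TRB role=C
GATATTGGGCTTAGTCTGCATCCGAACATATCTTGCTACGCCTGCATAGTCAAGCCCATGCCGTCGGTCACGTATGTAACCGAACGCCTGATCGGAGCCTACTGAATTCGTGTTATCAGACACGACAGGAAGCTGCTCTATTTGGTTCAA
>TRBC2 locus=TRB role=C
TTAATCTGACCGGACTTTTCTTAGGATACTTAGTATCCATTGATTCCTTCACGAGATGAGGTCGCCCGTATAATAGAGAATCCTCACGCCAGAAGACCGAGTGAAACGCCATCGATCCTCTAACTGAGTCATACTTAAGTATGGCGGAGC
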