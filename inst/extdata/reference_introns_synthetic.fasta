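>alpha
GTCCGTAAAAACTCCTAAATACAGCAGTCGTTTTCTCGAAATGATCCTAGACACACAGAATCAGGTCCTAAGTTACGTTCTCGTGTCTGGCGCCAACAACAAAGCATAGTGCGTAACTTAGAATTTGGTGAAAACATTAATGCTACCGAATATGACACTTCAGGTCTAAATTGATGATAGCATCGATCTTTGGCGGAAACATGTTGCTAAACGCTCCTTCCACATCGGTGCTGCAAAGTTTTGTTGAACGATACACAAGTTGGATTACGTTACTGCTATGTAACCAGGTGTCGTAGTCACTAACTATACATTTTTCCCTTTCACAAAACCATAATACTGCAAATCTTGAACAGTTTGACTTTGTGAATATCTGATCAGATTCAAATCTAGTCAATTAAAG
>beta
GTCAATAATGTCCGAAGGAAAATGCCACCTGAAACTGATGCCTCTTTATTTACGCGAGAGGTGTGTTTGCAAATTGGAATATCCGAGGTGTCTACGTAGGTCGCCTTCAGGTCTACATAAACTGCCCTAAAAGATACTCGTTATAACTAGGGCCGACTAATACACGTCATCAGGCTAAACGTTTCGACATTAGGTGAACAAATCCCAAGGTATGCCTAAAGACAATCAGTATATCCCAACTCGTGATCTCTCAAGACATCAAACAGACCACATTGGCTGTCTGGGTTGCGAACATTTCGTTCATTCTTATCGCCTCCCCGTCCGTATAGGCCCGAGAATATGAGCCAGTCTGATATCCAAGTATCCACTGTGTAGATACGGTAGGATATAAGGTTCATGTTATATAGAAG
>gamma
GTACTTATAACTTACAACTCCCCATGCGTTTTAGCTGGATAGCCTCTTCTTGATCTGCCCTATTTCGATTCACCTAGTCAATGCAGTAGCAAAGGGCGGTAATGAATGATTAAGCCTTACAAATCGATGTTACTTGCCTGTAGATAGGTTTTTAACTTAACAATCGAAATTTCATGCGACATAACGCCATGCAAAGTGGGACTGAGCCCATCGTGGATTTGGTTATCTCGCACTACCGGTATAACGTCTGTATACTTGCGCTCACGATGCAATGGATGAATGACTTATACGTAGATAATCTTTATGGTCTTTTAAAATCAAAGGCCCGCGTATAGAAGTTAATATCTTATTATCAGATATAACTGTAATTAATTTACAATCCTTATTAGGGTCCAGATCACCGAG
>delta
GTTTCAGCGTCCCCCTACAGAGATGAATGTTACATAGACTACGTTATTAATGCGCGTCTAATAATAGTATACATTTCGCTACTTGAAGCCCTTTGGTGTATTGTGCTGGTCCTCTCCGATATATGTATTCTAACCGTTTATGGATCACGCAGTGAGTATCTCGTAGTATATTCTCAACTGTTCACGTGAAACGCTCAGAACACCGTTAGGCTGTTCAAAGCAATGGGTAAATTCCGAGTATGGAATTTAACCAGGTCAGTTATTACAGACTGGACGGAATGGACCTGTGATATATGACCTTCTATAGATTGAGGCTGATGGTGCACTGTAAGTTCTCGCTAGCTTATCACATAGAGCAAAGCAGCTTCTAATGAGCATTGTAAACATGTGACAACCAG
>epsilon
GTGACAAAATGGTTTCTCATGATATATCAAACGGTCTGAAATACATTTCAATAGGGATGTATCTCTCCTTCTATTTGTTGGGGGAGGAATGCTACCAATATTGAGTTAATATTTGCCTCTGTGTAGGGTGGAACTAGTAAAAAAATACAGCCCAATCTGAAACAGACACAGCTGCCGAAGTGTTATCTCTTTGTTTCGGATTCAAGCGCAGGTGAGATCGAAGTGTTCTCCAAGTGTCATAACCCATTAGTATAAGATGTAATTCTTAGGGAAGCTTATGGAGTATTCGGATTCTGCAATTTAATGTCTCTCTGCATAACGGACCTCTGTACGATTCCGTCTAGTAAACCGTTAACGATAGATAGTCAAGTCTAAGCAGCCTTGAGTTTGTCTAGCTTATAG
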