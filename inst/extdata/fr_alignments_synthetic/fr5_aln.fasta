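>D1y
AAGGATGTGCGGTGGAGCCCAACTGCCTGAGATCATAGGGCGATTTTTTCTCTTTTATTAACTGTTAAAGTTCAGAATTAGTTTTGTATATGTAATTGTATATACACTTTGATGTCCCTGTGTCAGTACAATATAACCGTTCTAATACAACCACGAATGAACATCGATGAAACACACCTGTTGCCACATCTGTTAGTCCCTGTTTATCTACGGAAAGTATGGTCTTGAAGTTGCTAAGATCGTCTACATCATGTATTACGCCTGAAGCTAATGTTTCCATTCAGTAAACTACCGATACTCGTTAAAGTCATTTTCCATACGACAATTGATTGGGCTACAAGTAGATCGGCTTTGAAGGCGTGAGAACGTTTTTAATATCGAAAGGAGAATTATAATTTAA
>D1g
CAGGATGTGCGGTGGAGCCCAACTGCCTGAGATCATAGGGCGATTTTTTCTCTTTTATTAACTGTTAAAGTTCAGAATTAGTTTTGTATATGTAATTGCATACACACTTTGATGTCCCTGTGTCAGAAATATATAGCCGTTCTAATACAACCACGAATGAACATAGATGAAACACAACTGTTCCCAAATCTGTAAGTCCCTGTTTATCTACGGAAAGTATGGTCTTGAAGTTGCTAAGATCGTCTACGTCATGTATTACGCCTGAGGTTAATGTTTCCATTCAGTAATCAACCGATACTCGTTAAAGTCATTTTCCATACGACAATTGATTGGGCTACAAGTAGAACCGCTTTGAAGGCGTGATAACGTTTATAATATCCAACGGAGAATTATAATTTAA
>D1b
AAGGATGTGCGGTGGAGCCCAACTGCCTGAGATCATAGGGCGATTTTTTCTCTTTTATTAACTGTTAAAGTCCAGAACTAGTTTTGTATATGTAATTGCATATACACTTTGATGTCCCTGTGTCAGTACTATATAACCGTTCTAATACAACCACGAATGAACATCGACGAAACTCACCTGTTACCACATCTGTAAGTCCCTGTTTATCTACGGAAAGAATGGTCTTGAAGTTGCTAAGATCGTCTACATCATATTTTACGCCTGAGACTAATGTTTGCATTCAGTAAACTACCGATACTCGTTACAGTCATTTTCCATACGACAATTGATTGGGCTACAAGTAGAACGGCTTTGAAGGCGTGAGAACGTTTATAATATCGAAAGGAGAATTATAATTTAA
>D1e
AAGGATGTGCGGTGGAGCCCAACTGTCTGAGATCGTAGGGCGATTTTTTGTCTTTTATTAACTGTTGAAGTTCAGAATTAGTTTTGTATATGTAATTGCATATACACTTTGATGTCCCCGTGTCAGTACTATATAACCGTTCTCATACAACCACGAATGAACATCGATGAAACACACCTGTTCCCACATCTGCAAGTCCCTGTTTATCTACGGAAATTGTGGTCTTGAAGTTGCTAAGATCGTCTACATCATGTGTTACGCCGGAGGCTAATGTTTCAATTCAGTAAACTACCGATACTCGTTAAAGTCATTTTCCATACGACAATTGTTTGGGCTACAAGTAGAACGGCTGTGAAGGCGTGAGAACGTTTATAATACCGAAAGGAGAATTATAATTTAA
>D1d
AAGGATGTGCGGTGGAGCCCAACTGACTGAGATCATAGGGCGATTTTTTCTCTTTTGTTAACTGTTAAAGTTCAGAATTAGTTTTGTACATGTAATTGCATATACACTTTGATCTCCTTGTGTCAGTACTATATAACCGTTCTAATACAACCACGAATGAACATCGATGGAACACACCTGTTCCCACATCTGTAAGTCCCTGTTTATCTAAGGAAAGTATGGTCTTGAAGTTGCTAAGATCGTCTACATCATGTATTACGCCTTAGGCTAATGTTTCCATGCAGTAAACTACCGATACTCGTTAAAGTCATTTTCCATACGACAATTGATTGGGCTACAACTAGAACGGCTTTGAAGGCGTGAGAACGTTTATAATATCGAAAGGCGAATTATAATTAAA
>D1f
AAGGATTTGCGGTATAGCCCAACTGCCTGAGATCATAGGGCGATTTTTTCTCTTTTATTAACTGTTAAAGTTCAGAATTAGTTCTGTATATGTAATTGCATATACACTTTGATGTCCCTGTGTCAGTACTATATAACCGTTCTAATACAACCACGAATGAACATCGATGAAACACACCTGCTCCCACATCTGTAAGTCCCTGTTAATCTACGGAAAGTATGGTCTTGAAGTTGCTAAGATCGTCCACCTCATTTATTACGCCTGAGGCTAATGTTTCCATTCAGTAAACTACCCCTACTCGTTCAAGTCATTTTCCATACGACAATTGATTGGGCTACAAGTAGAACGACTTTGAAGGCGTGAGAACGTTTATAATATCGAAAGGAGAATTATAATTTAA
>D1h
AAGGATGTGCGGTGGAGCCCAACTGCCTGAGATCATAGGGCGATTTTTTCTCTTTTATTAACAGTTAAAGTTCACAATTAGTTTTGTATATGTAATTCCATATACACTTTGGTGTCCCTGTGTCAGAACTATATAGCCGTTCTAATACAACCACGAATGAACATCGATGAAACACACCTGTACCCACATCTCTAAGCCCCTGTTTATCTACGTAAAGTATGGTCTTGAAGTTGCTAAGATCGTCTACATCATGTATTACGCCTGAGGCTAATGTTTCCATTCAGTAAACTACCGATACTCGTTAAAGTCATTTTCCATACGACAATTGATTGGGCGACAAGTAGAACGGCTTTGAAGCCGTGAGAACGTTTATAATATCGAAAGGATAATTATAATTTAA
>B8
AAGGATGTGCGGTGGAGCCCAACTGCCTGAGATCATAGTGCGATTTTTTCCCTTTTATTAACTGTTAAAGTTCAGAATTAGTTGTGTATATCTAATTGCATATACACTTTGATGTCCCTGTGTCAGTACTATATAACCGTTCTAATACAACCACGAATGAACATCGATGAAACACACCTGTTCCCACATCTGTAAGTCCCTGTTTATCTACTGAAGGTATGGTCTTGAAGTTGCTAAGATCGTCTACAGCATGTATTACGCCTGAGGCTAATGTTCCCATTCAGTAAACTACCGATACTCGTTAAAGTCATTTTCCATACGACGATTGATTGGGCTACAAGTAGAACGGTTTTGAAGGCGTGAGAACGTTTATAATATCGAAAGGAGAATTATAATTTAC
>B8a
AAGTATGTGCGGTGGAGCCCACCTGCCTGAGAACATAGGGCGATTTTTTCTCTTTTATTAACTGTGAAAGTTCAGAATTAGTTTTGTATATGTAATTGCATATACAGTTTGATGTCCCTGTGTCAGTACTATATAACCGTTCTAATACAACCACGAATGAACATCGATGAAACACACCTGTTCCCACATCTGTAAGTCCCTGTTTATCTACGGAAAGTGTAGTCTTGAAGTTGCTAAGATCGTATACATCATGTATTACGCCTGAGGCTAATGTTTCCATTCAGTAAACTACCGATACTCGTTAAAGTCATTTTCCATCCGACAATTTATTGGGCTACGAGTAGAACGGCTTTGAAGGCGTGAGAACGTTTATAATATCGAAAGGAGAATTATAATTGAA
>C4
AAGGATGTGCGGTGGAGCCCAACTGCCTGAGATCATAGGGCGATTTTTTCTCTCTTTTTAACTGTTAAAGTTCAGAATTAGTTTTGTATATGTAATTGCATACACACTTTGATGTCGCTGTGTCAGGACTATATAACCGTTCTAATACAGCCACGAATGTACATCGATGAAACACACCTGTTCCCACATCTGTAAGTCCCTGTTTATCTACCGAAAGTATGGTCTTGAAGTTGCTAAGATCGTCTACATGATGTATTACGCCTGAGGCTAATGTTTCCCTTCAGTAAACTACCGATACTCGTTAAAGCCATCTTGCATACGACAATTGATTGGGCTACAAGTAGAACGGCTTTGAAGGCGTGAGAACGTTTATAATATCGAAAGGAGAATTATAATTTAA
>C4a
AAGGATGTGCGGTGGAGCCCAACTGCCTGAGATCACAGGGCGATTTGTTCTCTTTTATTAACTGTTAAAGTTCAGAATTAGTTTTGTATATGTAATTGCATATTCACCTTGATGTCCGTGTGGCAGTGCTATATAACCGTTCTAATACAACCACGAATGAATATCGAAGAAACACACCTGTTCCCACATCTGTAAGTCCCTGTTTATCTACGGAAAGTATGGTCTTGAAGTTGCTAAGATCTTCTACATCATGTATTACGCCTGAGGCTAATGTTTCCATTCAGTAAACTACCGATACTCGGTAAAGTCATGTTCCATACGACAATTGATTGGGCTACAAGTAGAACGGCTTTGAAGGGCTGAGAACGTTTATAATATCGAAAGGAGAATTATAATTCAA
>E2
AAGGATGTGCGGTGGAGCCCACCTGCCTGCGACCATAGCGTGATTTTGTCTCGTATATTAACAGTTAAGGTTTCCAATTAGTTTTATATATGTAATTGCATATACACTTTGATGTACCGCTGTGATTACTATATAACCGTTCGAATTCAACCATGACTGGGCATCGCTACAGCCCACCTGGCCCAATATCTCTAAGTACATGTTTATTTAGGTGAAATAAGGTCTTGAAGTTACTAAATGCATCTCCATCCTGTATGACACATGACGCCAACCTCTACGTTCAGTATACTACCAATACTCTTTACAGTCATGTTCCATACTACAATGGCGTGGGCTACAAGGAGAACGGCTTTTAAGACGTGAAAACCTATATAATATCGAAAGGAGAATGATAATTTAC
>E2a
AAGGATGTGCGGTGGAGCCCACCTGCCTGCGACCATCGCGTGATTTTTTCTCGTATATTAACAGTTAAGGGTTCCAATTAGTTTTCTATATGTAATTGCATATACACTTTGGTGTACCTCTGTGATTACTATATAACTGTTCGAATTCAACCATGATTGGGCATCGCTAAGGCCCACCTGGCCCAATATCTCTAAGTACATGTTTATTTAGGTGAAATAAGGTCTTGAAGTTACTAAATGCATCTCCATCCTGTATGACACATGAGGCCAACCTCTACGTTCAGTATACTACCAATACTCTTTACAGTCATGTTCCATACTACAATGGCGTGGGCTCCAAGGAGATCGGCTTTGAAGGCGTGGAAACCTATATAATATCGAAAGGAGAATGATAATTTAC
>E2b
AAGGATGTGCGGTGGAACCCACCTGCCTGCGACCATAGCGTGATTTTTTCTCCTATATTAACAGTTAAGGTTTTCAATTAGTTTTATATATGTAATTCCATATACACTTTGATGTACCTCTGTGTTTACTATATGACCGTTCGAATTCAACCATGATTGGGCATCGCTAAAGCCCACCTGGCCCAATATCTCTAATTACATGTTTATTTAGGTGAAATAAGGTCTTGAAGTTACTAAATGCATCTACATCCTGTATGACACATGAGGCCAACCTCTAAGTTCAGTATACTACCAATACTCTTTACAGTGATGTTCCATACTACAATGGCGTGGGCTACAAGGATAACTGCTGTGAAGGCGTCAAAATCTATATAATATAGAAAGGAGAATGCTAATTTAC
>01
AAGGATGTGCGGTGGAGCCCACCTGCCTGCGACCATAGCGTGATTTTTTCTCGTATATTAACAGTTAAGGTTTCCAATTAGTTTTATATATGTAATTGCATATACACTTTGATGTACCTCTGTGATTACTATATAACCGTTCGAATTCAACCATGATTGGGCATCGCCAAAGCCCACCTGGCCCAATATCTCTAAGTACATGTTTATTTAGGTGAAAAAAGGTCTTGAAGTTACTAATTGCATCTACATCCAGTATGACACATGAGGCCAACCTCTACGTTCAGTATACTACAAATACTCTTTACAGTCATGTTCCATACTACAATGGCGTGGGCTACAAGGAGAACGGCTTTGAAGGCGTGAAAACCTATATAATATCGAAAGGAGAATGATAATTTAC
>A2
AAGGATGTGCGGTGGAGCCCACCTGCCTGCGACCATAGCGTGATTTCTTCTCGTATATTAACATTTAAGGTTCCCAATTAGTTTTATATATGTAATTGCATATACACTTTGATGTACCTCTGTGATTACTATGTAACCGTTCGAATTCAACCATGATTGGGCATCGCTAAAGCCCACCTGGCCCAATATCTCTAAGTACATGTGTATTTAGGTGAAATAAGGTCTTGAAGTTACTAAATGCATCTACATACTATATGACACATGAAGCCAAGCTATACGTTCAGTATACTACCAATACTCTTTACAGTCAAGTTCCATACTACAATGGCGTGGGCTACAAGGAGAACGGCTTTGAAGGCGTGAAAACCTATATAATATCGAAAGGAGAATGATAATTTAC
>A2a
AAGGATATGCGGTTGAGCCCACCTGCCTGCGACCATAGCGTGATTTTTTCTCGTATATTAACAGTTAAGGTTCCCAATTAGTTTTATATAAGTAATTGCATATACACTTTGATTTACCTCTGCGATTACTATATAACCGTTCGAATTCAACCATGATTGGGCATCGCTAAAGCCCACCTGGCCCAATATCTCTAACTACATGTTTATTTCGGGTAAATAAGGTCTTGAAGTTACTAAATGCATCTACATCCTGTATGACACATGAGGCCAACCTCTACGTTCAGTATACTACCAATACTCTTTACAGTCATGTTCCATATTGCAATGGCGTGGGCTACAAGGAGAACGGCTTTGAAGGCGTGAAAACCTATCTAATATCGCAAGGAGAATGATAATTTAC
>LvTrf
AGAGATGTGCCGTAGATACCCACTGCTTGGGATCAGACCGAGCTTTTGTCGCTTATCCTATGGGAAAAACTGCACAATTAGTATTATCCGTCTAGTTGCACAGACACCTTGGGGGAACTCTGTCAATACTATCGAACCCATCTAATCCCTACACGCATAAGAATCGCAAGGAAAGTCCTGTACTAATATTATTAAGTCGATGTTTATTTGCGTAACATTTGGTCTCGAAGTTAGTAACTCCATCCACTTGATATATTAACCAGTAAGATAATTACTCCCTACAGTTGACTACCGATACTCTTTAAAATGATTATTCCTGTGGCCATCGATTCGGCTCCAAGCAGAACTAGTTCGAAGTCGTGAACACCTATATAATATAGACAAGACCATGGAGATATGC
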