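>D1y
AAGAGCTGAATCTTCTTGTACTCAAATGCTACATCCAATAGGATTGATTCCACTATGCGCTGTTCCATACACGGTCAAGGATGTAAATAAACAAGTTCATATGAAAAAGCTCGTTGAAAACCTAGAAATACGAACCGCTGCCTTGAACTGGCTGGGACCGCGTGAGTCCCCTACCAACTGGCCGCCGCCTGTTTGCATACTCTGTCAAATGATTAGTGTACCTTGCGTGAAGGTGCTAGGCCTGTAGTGTCACTCCCACCAGCACACTACAATAGAGTTCCGCAAGTGTCAACTTTATATTTACCAGTACTGCGGTAGTGGTTCAAGACTACGGTCAGTTTTGAACATTGTCTAAATTAATGGAAAAACCACCAACCTATTAGCGAAAACAAGAATCAGT
>D1g
AAAAGATGAATCTTCTTGTACTCAAATGCTACATCCAATAGGATTGATTCCACTATGCGCTGTTCTATACACGGTCAAGGATGTAAATAAACAAGTTCATATGAAAAAGCTCGTTGAAAACTTAGAAATACGAACCGCTGCCTTGAACTGGCTGGGACCGCGTGAGTCCCGTACCAACTGGCCGCCGCCTGTTTGCATACTCTGTCAAATGATTTGTGTCACTTGCGTGAAGGTGCTAGACCTCTAGTGTCGCTCCCAGCACCACTATACAATAGAGTTACCCAAGTGTCAACTTTATATTTACCAGTACTGCGGTAGTGGTGCAAGACTACGGTCAGATTTGAACATTGTCTAAATTAATGGAAAAACCACCAACCTATTAGCGAAAACTAGAATCAGT
>D1b
AAAAAAAGAATCTTCTTGTACTCAAATGCTACATCCAATAGGATTGATTCCACTATGCGCTGTTCCATACACGGTCAAGGATGTAAATAAACAAGTTCATAAGAAAAAGCTCGTTGAAAACTTAGGAATACGAACCGCTGCCTTGAACTGGCTGGGCCCGCGTGAGTCCCCTACCAACTGGCCGCCGCCTGTTTGGATACTCTGTCAAATGATTTGTGTACCTTGCGTGAAGGTGCTAGACCTGTAGTGTCACTCCCACCAGCACTCTACAATAGAGTTACGCAAGTGTCAACTTTATATTTACCAGTACAGCGGTACTGGTTCAAGACTACGGTCAGTTTTGAACATTGTCTAAATTAATGGAAAAACCACCAACCTTTTAGCGAAAACAAGAATCAGT
>D1e
AAAAGGTGAATCTTATTGTACTCAAATGCTACATCCAATAGGCTTGATTCCACTATGCGCTGTTCCATACACGGTCATGGATGTAAATAAACAAGTTCATATGAAAAAGCTCGTTGAAAACTTAGAAATACGAAGCGCTGCCTTGAACTGGCTGGGACCGCGTGAGTCCCCTACCAACTGGCCGCCGCCTGTTTGCATACTCTGTCAAATGATTTGTGTACCTTGCGTGAAGGTGCTAGACCTGTAGTGTCACTCCCACCATCACTCTACAATAGAGTTACGCAAGTGTCAACTTTGTATTTACCAGTACTACGGTAGTGGTTCAAGACTACGGTCAGTTTTGAACATTGTCTAAATTAATGGAAAAACCACCAACCTATAAGCGAAAACAAGAATCAGT
>D1d
AAAAGATGAATCTTCTTGTACTCAAATGCTAAATCCAATAGGATTGTTTCCACTATGCGCTGTTCCATACACGGTCAAGGATGTAAATAAACAAGTTCATATGTAAAAGCTCGTTGAAAACTTAGAAATACGAACCGCTGCCTTAAAGTCGGTGGGAGCGCGTGAGTCCCCTACCAACTGGCCGCCGCCTGTTTGCATACTCTGTCAAATGATTTGTGCAGCTTGCGTGAAGGTGCTAGACCAGTAGTGTCACTCCCACCAGCACTCTACAATAGAGTTACGCAAGTGTCAACTTTATATTTACCAGTACTGCGGTAGTGGATCAAGACTACGGTCAGTTTTGAACATTGTCTAAATTAATGGAAAAACTACCAACCTATTAGCGCAAACAAGAATCAGT
>D1f
AAAAGATGAATCTTCTTGTACTCAAATGCTACATCCAATAGGATTGATCCCACTATGCGCTGTTCCATACACGGTTAAGGATGTAAATAAACAAGTTCATATGAAAACGCTCGTGGAAAACTTAGAAATACGAACCGCGGCCTTGAACTGGCTGGGACCGCGTGAGTCCCCTACCAACTGGCCGCCGCCTGTTTGCATACTCTGTCAAATGATTTGCGTACCTTGCGTGAAGGTGCTAGACCTGTAGTGTCACTCACACCAGCACTCTACAATAGAGTTATGCAAGTGTCAACTTTATATTTACCAGTACTGCGGTAGTGGTTCAAGACTACGGTCAGTTTTGAACATTGGCTAAATTAATGGAAAAACCACCAACCTATTATCGAAAACAAGAATCAGT
>D1h
AAAAGATGAATCTACTTGTACTCAATTGCTACATCCAATAGGATTAATTCCACTATGCGCTGTTCCATACACGGTCAAGTATGTAAATAAACAAGTTCATCTGAAAAAGCTCGTTGAAAACTTAGAAATACGGACCGCTGCCTTGAACTGGCTGGGACCGCGTGAGTCCCCTACCAAGTGGCCGCCGCCTGTTTGCATACTCTGTCAAATGATTTGTGTACCTTGCGTGAAGGTGCTAGACCTGTAGTGTCACTCCCACCAGCACTCTACAATAGAGTTACGGAAGTGTCAACTTTAAATTTACCAGTACTGCGGTAGTGGTTCAAGACTACGGTCAGTTTTGAACATTGTCTAAATTAATGGAAAAACCACCAACGTATTAGCGAAAACAAGAATCAGT
>B8
AAAAGACGAATCTTCTTGTACTCAAATGCTACATCTAATAGGATTGATTCCACTATGCGCTGTTCCATACACGGACAAGGATGTAAATAAACAAGTCCATATGAATAAGCTCGTTGAAAACTTAGAAATACGAACCGCTGCCTTGAACTGGCTGGGACCGCGTGAGTCCCCTAATAACTGGCCGCCGCCTGTTTGCATACACTGTCAAATGATTTGTGTACCTTGCGTGAAGGTGCTAGACCTGTAGTGTCAATCCCAACAGCACTCTACAATAGAGTTAGGCAAGTGTCAACTTTATATTTACCAGTACTGCGGTAGTGGTTCAAGACTACGGTCAGTTTTGAATATTGTCTAAATTAATGGAAAAACCACCAACCTATTAGCGAAAACAAGAATCAGT
>B8a
AAAAGATGAATCTTCTTGTACTCAAATGCTACATCCAATAGGATTGATTCCACTATGCGCTGTTCAATACACGGTCAAGGATGTAAATAAAGAAGTTCATATGAAAAAGCTCGTTGAAAACTTAGAAATACTAACCGCAGCCTTGAACTGGCTGGGACCGCGTGAGTCCCCTACCAACTGGCCGCCTCCTGTTTGGATACTCTGTCATATGATTTGTGTACCTTGCGTGAAGGTGCTAGAGCTGTAGTGTCACTCCCACCAGCACTCTACAATAGAGTTACGCAAGTGTCAACTTTATATTTACCAGTACTGCGGTAGTGGTTCAAGACTACGGTCAGTTTTGAACATTGTCTAAGTTAATGGAAAAACCACCAACCTATTAGCGAAAACAAGAATCAGT
>C4
AAAAGATTTATCTTCTTGTACTCAAATGCTACATCCAATAGGATTGATTCCACTATGCGCTATTCCATACACGGTCAAGGATGTAAATAAACAAGTTCATATGAAAAAGATCGTTGAAAACTTAGAAATACGAACCGCTGCCTTGAACTGGCTGGGACCGCGTGAGTCCCCTACCAACTGGCCGCCGCCTGTTTGCATACTCTGTCAAATAATTTGTGTACCTTGCGTGAAGGTGCTAGACCTGTAGTGTCACTCCCACCAGCACTCAACATTAGAAATACGCAAGTGTCAACTTTATATTTACCAGTACTGCGGTAGTGGTTCAAGACTACGGTCAGTTTTGAACATTGTCTAAATTAATGGAAAAACCGCCAACCTATTAGCGAAAACAAGAATCAGT
>C4a
AAAAGATGAATCTTCTTGTACTCAAATGCTACATCCAATAGGATTGATTCCACTATGCACTGTTCCATACACGGTCAAGGATGTAAATAAACAACTTCATATGAAAAAGCTCGTTGAAAACTTAGAAATACGAACCGCTGCCTTGAACTGGCTGGGACCGCGTGAGTCCCCTACCAACTGGCCGCCCCCTGTTTGCATACTCTGTCAAATGATTTGTGTACCTTGCGTGAAGGTGGTAGACCTGTAGTGTCACTCCCACCGGCCCTCTACAATAGAGTTACGCAAGTGTCAACTTTATATTTACCAGTACTGCGGTAGTTGTTCAAGACTGCGGTCAGTTTTGAACATTGTCTAAATTAATGGAAAAACCACCAACCGATTAACGAAAACAAGAATCAGT
>E2
AAAAGATGCATCTCCCTGTACTCAAAGGCTATATCCAATAGGATTCATGCTATTCGGCGCTGTTCCATACACGGTCAAGGATGTAAATAAACATGTTAAAATGAAAAAGTTTATTGAAAACCTAGAGATACGAACCCCTGTCTGGAACTAGCTGCGACCGCGTGAGTCGATAACTAACTGGACGCCTTCTATTTACACGGTCTGTCAAATGATTTGTGTACATGGCGGGATGGTGCTAGAACTGTAGTTACTCTCCCACCAGCATTCTCCAATAGCGTTACGCAGGCGTTTACTTTATATTTAACAGTACAGCGGTAGTGGTTCAAGACTATCGTCAGTTTTGAACTTTGTCTAAATTAATGGAAGATTCACCAATCCACTAGCGTATACACGAATCAGA
>E2a
AAAAGATGTATCTACTTGTACTCAAGGGCTATATCCAATAGGATTCATGCTATTCGGCACTGTTCCATACACGGTCAAGGACGTAAATAAACATGTTAAAATAAAAAAGTTTGTTGAAAACCTAGAGATACGAACCCCTGTCTGGAACTAGCTGCGACCGCGTGAGTCGACAACTAACTGGACGCCTACTATTTACACTGTCGGTCAAACGATTTGTGTACATGGCGGGATCGTGCGAGAACTGTAGTTACTCTCCCACCAGCATTCTCCAATAGCGTTACGCAGGCGTTTGCTTTACATTTAACAGTATAGCAGTAGTGGTTCAAGACTATCGTCAGTTTTGAACTTTGTCTAAATTAATGGAAAATTTACCAATCCACTATCGTATACAGGAATCAGA
>E2b
AAAAGATGCATCTCCTTGTACTCAAAGGCTATATCCAATAGGATTCATGCTATTCGGCGCTGTTCCATACACAGGCAAGGATGTAAATAAACATGTTAAAATGAAAAAGTTTCTTGCAAACCTAGAGATACGAACCCCTGTCTGGAACTAGCTGCGACCGCGTGAATCGACAACTAACTGGACGCCTACTATTTACACTGTCTGCCAAATGATGTGTGTACATGGCGGGATGGTGCTAGATCTGTAGTTACTCTCCCACCAGCATTCTCCAATAGCGTTACGCAGGCGTTTACTTTATATTTCACAGTACAGCGGTAGTGGTTCAAGAGTATCGTCAGTTTTGAACTTTGTCTAAATTAATGGAAAATTCACCAATCCACTAGCGTATACACGAATCAGA
>01
AAAAGATGCATCTCCTTGGACTCAAAGGCTATATCCAAAAGGATTCATGCTATTCGGCGTTGTTCCATACTCGGTCAAGGATGTAAATAAACATGTTAAAATGAAAAAGTTTGTTGAAAACCTAGAGATACGAACCCCTGTCTGGAACTAGCTGCGACCGCGTGAGTCGACAACTAAATGGACCCCTACTATTTAGACTGTCTGTCAAATGATTTGTGTACATGTCGGGATGGTGCTCGAACTGTAGTTACTCTCCCACCAGCATTCTCCAATAGCGTTACGCTGGCGTTTACTTTATATTTAACAGTACAGCGGTAGTGGTTCAAGACTATCGTCACTTTTGAACTTTGTCTAAATTAATGGAAAATTCACCAATCCACTAGCGTATACACGAATCAGA
>A2
AAAAGATGCATCTCCTTGTACTGAAAGGCTATATCCAATAGGATTCATGCTATTCGGCGCTGTTCCATACACGGTCAAGGATGTAAATAAACATGTTAAAATGAAAAAGTTTGTTGAAAACCTAGAGATACGAACCCCTGTCTGGAACTAGCTGCGACCGCGTGAGTCGACAACTAACTGGACGCCTACTATTTACACTGTCTGTCAAATGATTTGTGTACATGGCGGGCTGGTGCTAGAACTGTAGTTACTCTCCCACCAGCATTCTCCAATAGCGTTACGCAGGCGTTTACTTTATATTTAACAGCACAGCGGTACTGGTTCAAGACTATCGTCAGTTTTGAACTTTGTCTAAATTAAGGGAAAATTAACCAATCCACTAGCGTATACACGACTTAGA
>A2a
AAAAGGTGCATCTCCTTGTACTCAAAGGCTTTAACCAATAGGATTCATGCTATTCGGCGCTGTTCCATACCCGGTCAAGGATGTAAATAAACATGTTCAAATGAAAAAGTTTGATGAAAAGCTAGAGATACGAATCCCTGTCTGGAACTAGCTGCGACCGAGTGAGTCGACAACTAACTGGACGCCTACTATTTACACTGTCTGTCAAATGATTTGTGTACATGGCGGGATGGTGCTAGAACTGTAGTTACTCTCCCACCAGCATTCTCCAATAGCGTTACGCAGGCGTTTACTTTAGATTTAACAGTACAGCGGTAGTGGTTCAAGACTATCGTCAGTTTTGAACTTTGTATAAATTCATGGAAAATTCAACAATCCACTAGCGTATACACGAATCAGA
>LvTrf
AAGAGCAAAAAAGCATTGTGCGCCAATGTCACTTCCGATAGGAGTCTCTCTACCCTGCGCATGCTCTTACACTTTCACGGTCCATATTAAACAGGTTAAGACGAAAAAGGACATTCAGAACTAAGAGATCCGTTCCGGTACATCCTACTCGCCGGCACCGCATGAATCGCCTAGTAGCTTGACGCCTACTAATGACACACACTTTCCGATGGCGTGTATACATTACATGAAGATGATAATCCTGTAGATCCACTACCTCGAGCTCTCCTCTGTTACATTACGTATCTGTTGACTTTGTTTTTAACAGGACAGCGCTACTCGTTCAAGACTATTGTCAACTGTGAACGTTTTCGTGATTAAAGGATAAACCACTAAGACATCAGTGTGTACAACGATCACT
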