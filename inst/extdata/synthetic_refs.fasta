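>upstream_box
TGCTCTTAAGCTTGCTACCTGGCAACAACATCTGAGGTCGTACTATACTGTAGGTTGAGCCCATAATGACTGGGATGCAC
ATTACGACGTGGTCTCCCTCTCCAG
>downstream_box
TGCTCTTAAGCTTGCTACCTGGCAACAACATCTGAGGTCGTACTATACTATAGGTTGAGCCCATAATGACTGGGATGCAC
ATTACGACGTGGTCTCCCTCTCCAG
>RHD_ex9
AAGCCACTAAACAGGGTATCGGAATAGTGGTCGCAACCGTCCATGGTTCGGGCCGAGACGGATAACTACTTACGTCTATA
GAGGCCCTTAGAGTTAGAGCGAAGACATGACATTGCCTAATAATGCAGAGTGTGCCAGTCGGTCTCGA
>RHCE_ex9
AAGCCACTAAACAGGGTATCGGTATAGTGGTCGCAACCGTCCATGGTTCGGGCCGACACGGATAACTACTTACGTCTATA
GAGGCCCTTAGAGTTAGAGCGAAGACATGACATTGCCTGATAATGCAGAGTGTGCCAGTCGGTCTCGA
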