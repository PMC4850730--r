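>synthetic_promoter_1 synthetic 120 bp promoter-like sequence with planted elements
AAACAGGTTTAGTCTTGACTATCCCAGATAAATGTGGCATTCCCATATGAAACAAGATAG
AAGATTGATAGGAAGAGTACTAGGTATTCATAGTGCTTCATGGAATCAAGTGATAATAAA
>synthetic_promoter_2 synthetic 120 bp promoter-like sequence with planted elements
TTGACCTTTAGCCACCAACTGTCCACCGTTTTACATGACTCGGTTGATAGTTGGCTCCCA
ATTGAGGACGGGACCGGGTCTTTGATAGATCAACTCCACCCTCCCGATAGGCATACGAGA
>synthetic_promoter_3 synthetic 120 bp promoter-like sequence with planted elements
TAGTCATCAGATAGCCTGCACTTGACCTTGACCGGCTACCTTACCGATGATAATTGTTCT
CAAGCAATCTCCCGAACAGCCTGCGTAGATTCTCCAGGCCAAGGGGCTCGGTTGACTCAG
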