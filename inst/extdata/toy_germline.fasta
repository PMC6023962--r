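>IGKV1 kind=V anchor=51 frame=0
CCTGGTACTCGCGGTTTGTATGGCGGGGACCACTGTGTCGGCGGAACGCGGTGTTCCTGG
>IGKV2 kind=V anchor=51 frame=0
ATCTCTATGACCATCCTCGTCGGGGGTATACTCAGCGCCAAAGGGGAAACTTGTGTCTTT
>IGKV3 kind=V anchor=51 frame=0
GTCTATGAAGCCTTAAGGAGCCATCTATGCTTTCAGACATTGAGCGGGAGCTGTCGAAGA
>IGKV4 kind=V anchor=51 frame=0
TTACATGAACGCACACATCTAGCCACCGTCCGAAGCGTTGTTACCCCCAATTGCATAGAG
>IGKV5 kind=V anchor=51 frame=0
GCTCACGACTCATCTAGTCAGACAGCGTCTGGGAAAAGCGACGGTGGGCAATGTTTATCG
>IGKV6 kind=V anchor=51 frame=0
AATTCTCGTTGCAAATTCCGCTCCCCGGACGCACCTTGTGGCGGCTGTTGGTGTATCGCT
>IGKV7 kind=V anchor=51 frame=0
GTTATGGGCGGATCACTGCAACAAGATTGCAAGATAATTTCATTACTCGAATGCACTAAA
>IGKV8 kind=V anchor=51 frame=0
GTCTCCCAATCCGCAGTACCGGGTAGAAGTCGTAGGCGGCTACCCGCACAATGTATCGCG
>IGKJ1 kind=J anchor=6 frame=0
TACTAATTCCGGACCTTACCACACCGAAAG
>IGKJ2 kind=J anchor=6 frame=0
AGAGTGTTTCTGACCGAACTAAGGAGACAA
>IGKJ3 kind=J anchor=6 frame=0
GCCCGATTTTCAGAGCAAAAAAGGCTATAC
>IGKJ4 kind=J anchor=6 frame=0
CTTCGGTTCTGTTGGGCGGCGCTCTCGATG
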