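>ref_5p8s_synthetic|synthetic 5.8S anchor (replace with a real 5.8S for real data)|unknown
TTCGTTGGGTGTGTCGGGGTGGAGATTCCTTTTCGGTACATGTATGTCGACAGCGCGGAAACCTCGAATA
AGGGGGTCTGGAACGGTACCCAAGCAAGTGCGCGGGCTATACAGCGCGTTCGGGGATTGCGCGCCCACGG
ATCGCCGCGTTGCTCGGACGACT
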