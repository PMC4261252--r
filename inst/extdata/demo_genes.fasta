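>x1
GCTAAATTGGACAAATCTCAATGAAATTGTCTTGG
>y1
ATGTCCTCGTCTTCGTCTACCGGGTACAGAAAA
>x2
CATGACTAAAGAAACGATTCGGGTAGTTATTTGGCGG
>y2
ATCTACAAGCGAACCAGAGTCTTCTGCAGGCTTAGAT
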