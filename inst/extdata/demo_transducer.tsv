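# worked-example weighted transducer over {G,C}: two accepting paths for
# input GGC / output CCG, with weights 1*2*3*6*1 + 1*3*1*4*1 = 48
initial	0	1
final	3	1
0	G	C	2	0
0	G	C	3	1
1	G	C	1	2
1	C	G	6	3
2	C	G	4	3
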