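category	n
1	284
2	23
3	13
4	17
5	19
6	53
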