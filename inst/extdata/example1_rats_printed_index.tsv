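group_id	A	rank
B	-1.665	4
C	1.043	1
D	-0.272	2
E	-0.382	3
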