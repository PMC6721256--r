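group_id	A	rank
g1	-0.094	1
g2	-0.346	2
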