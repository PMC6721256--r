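group_id	parameter	state	mean	sd	n
B	hexokinase	pre	13.8	1.2	10
B	hexokinase	load	7.1	1.7	10
B	ammonia	pre	103	11	10
B	ammonia	load	186	48	10
B	hcs11	pre	13.1	2.9	10
B	hcs11	load	30.8	6.8	10
B	glycogen	pre	702	215	10
B	glycogen	load	293	218	10
B	lactate	pre	6.1	2.0	10
B	lactate	load	16.6	8.5	10
C	hexokinase	pre	13.4	1.7	8
C	hexokinase	load	12.7	2.0	9
C	ammonia	pre	83	18	8
C	ammonia	load	127	73	9
C	hcs11	pre	8.1	2.9	8
C	hcs11	load	30.2	5.7	9
C	glycogen	pre	897	269	8
C	glycogen	load	451	147	9
C	lactate	pre	5.5	0.8	8
C	lactate	load	7.2	1.4	9
D	hexokinase	pre	14.2	1.1	9
D	hexokinase	load	5.5	2.3	9
D	ammonia	pre	79	13	9
D	ammonia	load	110	34	9
D	hcs11	pre	8.9	1.2	9
D	hcs11	load	31.9	2.6	9
D	glycogen	pre	745	173	9
D	glycogen	load	225	124	9
D	lactate	pre	5.2	1.1	9
D	lactate	load	12.5	6.2	9
E	hexokinase	pre	13.1	2.8	8
E	hexokinase	load	8.6	1.4	8
E	ammonia	pre	73	18	8
E	ammonia	load	112	51	8
E	hcs11	pre	10.9	1.5	8
E	hcs11	load	28.8	2.5	8
E	glycogen	pre	757	165	8
E	glycogen	load	387	153	8
E	lactate	pre	5.5	1.1	8
E	lactate	load	9.8	7.4	8
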