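group_id	parameter	contribution
B	hcs11	1.060
B	hexokinase	-0.445
B	lactate	-1.163
B	ammonia	-0.715
B	glycogen	-0.402
C	hcs11	2.120
C	hexokinase	-0.048
C	lactate	-0.209
C	ammonia	-0.473
C	glycogen	-0.347
D	hcs11	2.010
D	hexokinase	-0.500
D	lactate	-0.946
D	ammonia	-0.350
D	glycogen	-0.486
E	hcs11	1.273
E	hexokinase	-0.315
E	lactate	-0.527
E	ammonia	-0.473
E	glycogen	-0.340
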