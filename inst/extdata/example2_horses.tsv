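group_id	parameter	state	mean	sd	n
g1	p95	pre	375	14	6
g1	p95	load	393	20	6
g1	p95	recovery	380	16	6
g1	p50	pre	170	5	6
g1	p50	load	185	3	6
g1	p50	recovery	176	19	6
g1	hemoglobin	pre	16.5	0.2	6
g1	hemoglobin	load	16.9	0.7	6
g1	hemoglobin	recovery	16.5	0.2	6
g1	heart_rate	pre	37.0	1.5	6
g1	heart_rate	load	112.9	2.7	6
g1	heart_rate	recovery	39.0	2.9	6
g1	lactate	pre	50.2	28.9	6
g1	lactate	load	55.5	14.9	6
g1	lactate	recovery	50.8	7.1	6
g1	alkalinity	pre	550	19	6
g1	alkalinity	load	550	26	6
g1	alkalinity	recovery	560	20	6
g2	p95	pre	330	11	6
g2	p95	load	333	9	6
g2	p95	recovery	325	7	6
g2	p50	pre	163	5	6
g2	p50	load	166	4	6
g2	p50	recovery	161	3	6
g2	hemoglobin	pre	15.1	0.2	6
g2	hemoglobin	load	16.0	0.5	6
g2	hemoglobin	recovery	15.3	0.5	6
g2	heart_rate	pre	42.5	3.2	6
g2	heart_rate	load	129.2	2.9	6
g2	heart_rate	recovery	45.0	6.1	6
g2	lactate	pre	59.0	29.9	6
g2	lactate	load	92.3	13.5	6
g2	lactate	recovery	64.2	19.0	6
g2	alkalinity	pre	475	22	6
g2	alkalinity	load	430	22	6
g2	alkalinity	recovery	465	11	6
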