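group_id	parameter	S	response_signed	recovery
g1	p95	0.963	0.048	0.385
g1	p50	0.971	0.088	0.667
g1	hemoglobin	0.988	0.024	0
g1	heart_rate	0.960	2.059	0.027
g1	lactate	0.424	-0.106	0.128
g1	alkalinity	0.965	0	1.000
g2	p95	0.967	0.009	0.625
g2	p50	0.970	0.018	0.400
g2	hemoglobin	0.987	0.059	0.286
g2	heart_rate	0.925	2.040	0.030
g2	lactate	0.493	-0.565	0.185
g2	alkalinity	0.954	-0.095	0.286
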