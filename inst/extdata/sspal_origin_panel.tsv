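line_id	pair_id	murine_pct	human_pct	str_result
JHU-LX82	pair5	99.4	0.6	failed
JHU-LX82	pair43	98.4	1.7	failed
JHU-LX21	pair5	96.6	3.4	failed
JHU-LX21	pair43	100.0	0.0	failed
MSK-LX38	pair5	99.2	0.8	NA
MSK-LX38	pair43	99.8	0.2	NA
NHJ29	pair5	94.5	5.5	failed
NHJ29	pair43	97.0	3.0	failed
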