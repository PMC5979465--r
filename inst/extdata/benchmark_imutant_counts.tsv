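class	tp	fn	fp
increase	0	6	1
decrease	22	4	11
no_effect	2	6	4
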