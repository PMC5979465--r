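class	tp	fn	fp
increase	3	20	16
decrease	66	26	36
no_effect	22	28	22
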