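class	tp	fn	fp
increase	23.2	18.6	51.8
decrease	91.4	63.2	37.0
no_effect	30.8	52.6	45.6
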