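sample_id	habitat	season	replicate
H	H	1	1
R	R	1	1
L	L	1	1
B	B	1	1
S	S	1	1
N	N	1	1
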