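# editing factor PPR56-like
S-13	S	T	N
P-12	P	N	D
L-11	L	M	D
S-10	S	T	D
P-9	P	T	N
L-8	L	V	T
S-7	S	T	D
P-6	P	N	D
L-5	L	L	D
S-4	S	T	N
P2-3	P2	N	D
L2-2	L2	V	D
S2-1	S2	N	D
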