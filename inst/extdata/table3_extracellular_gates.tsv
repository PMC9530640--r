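member	res1	res2	res3	res4	res5
BbZIP	A102	S106	P199	L200	A203
hZIP3	T58	A62	S199	L200	G203
hZIP1	T83	D87	E209	L210	A213
hZIP2	A59	H63	Q194	L195	A198
hZIP11	A54	S58	N232	L233	G236
hZIP9	T49	V53	I177	V178	A181
hZIP7	D157	H161	L324	T325	T328
hZIP13	N88	H92	L217	T218	A221
hZIP12	D392	H396	T549	T550	A553
hZIP4	D353	H357	A506	T507	A510
hZIP8	N154	Q158	S313	T314	A317
hZIP14	N171	Q175	S338	T339	A342
hZIP6	D344	H348	S599	T600	A603
hZIP5	D236	H240	S391	T392	A395
hZIP10	D429	H433	S676	T677	A680
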