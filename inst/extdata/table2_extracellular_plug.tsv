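member	res1	res2	res3	res4	res5
BbZIP	M99	A102	L200	I204	M269
hZIP3	F55	T58	L200	V204	F273
hZIP1	F80	T83	L210	L214	F283
hZIP2	F56	A59	L195	V199	F269
hZIP11	M51	A54	L233	I237	M302
hZIP9	L46	T49	V178	I182	F254
hZIP7	L154	D157	T325	V329	F401
hZIP13	L85	N88	T218	I222	F296
hZIP12	L389	D392	T550	I554	F618
hZIP4	V350	D353	T507	V511	F575
hZIP8	L151	N154	T314	I318	F381
hZIP14	L168	N171	T339	I343	F406
hZIP6	L341	D344	T600	V604	F669
hZIP5	L233	D236	T392	V396	F461
hZIP10	M426	D429	T677	V681	F746
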