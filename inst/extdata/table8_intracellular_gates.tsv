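member	tm4_m5	tm7_m5	tm3_m6	tm3_m3
BbZIP	H177	E276	D144	H275
hZIP3	H180	E280	E102	L279
hZIP1	H190	E290	E127	L289
hZIP2	H175	E276	E120	L275
hZIP11	H204	D309	D96	D308
hZIP9	H155	H261	D123	V260
hZIP7	H329	S408	E208	V407
hZIP13	D228	N303	E134	V302
hZIP12	H528	E625	E439	V624
hZIP4	H485	D582	E395	C581
hZIP8	H292	D388	E191	A387
hZIP14	H317	D413	E208	A412
hZIP6	H578	D676	E410	V675
hZIP5	H370	D468	E278	V467
hZIP10	H655	D753	E487	V752
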