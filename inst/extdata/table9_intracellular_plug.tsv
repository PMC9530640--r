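member	phi1	phi2	phi3	phi4
BbZIP	F170	A218	V272	V277
hZIP3	L173	S218	I276	I281
hZIP1	L183	R228	I286	I291
hZIP2	L168	R213	V272	I277
hZIP11	L197	A247	V305	I310
hZIP9	T148	F196	V257	V262
hZIP7	N296	I343	V404	V409
hZIP13	N189	I236	I299	V304
hZIP12	I521	V568	L621	M626
hZIP4	I478	A525	V578	M583
hZIP8	I285	I332	I384	M389
hZIP14	I310	I357	I409	M414
hZIP6	V571	V618	V672	M677
hZIP5	V363	M410	V464	M469
hZIP10	V648	V695	V749	M754
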