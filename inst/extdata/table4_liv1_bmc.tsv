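member	tm4_p3p	tm4_p1	tm4_p2	tm4_p3	tm5_p1p	tm5_p2p	tm5_p1	tm5_p2	tm5_p3
hZIP4	D482	H485	N486	D489	H514	E515	H518	E519	D522
hZIP12	D525	H528	N529	D532	H557	E558	H561	E562	D565
hZIP5	D367	H370	N371	D374	H399	E400	H403	E404	D407
hZIP6	D575	H578	N579	D582	H607	E608	H611	E612	D615
hZIP10	D652	H655	N656	D659	H684	E685	H688	E689	D692
hZIP7	D326	H329	N330	D333	H358	E359	H362	E363	D366
hZIP13	D225	D228	N229	H232	H257	E258	H261	E262	D265
hZIP8	D289	H292	N293	D296	E321	E322	H325	E326	D329
hZIP14	D314	H317	N318	D321	E346	E347	H350	E351	D354
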