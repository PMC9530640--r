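member	subfamily
BbZIP	reference
hZIP1	II
hZIP2	II
hZIP3	II
hZIP4	LIV-1
hZIP5	LIV-1
hZIP6	LIV-1
hZIP7	LIV-1
hZIP8	LIV-1
hZIP9	I
hZIP10	LIV-1
hZIP11	GufA
hZIP12	LIV-1
hZIP13	LIV-1
hZIP14	LIV-1
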