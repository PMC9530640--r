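member	tm4_p3p	tm4_p1	tm4_p2	tm4_p3	tm5_p1p	tm5_p2p	tm5_p1	tm5_p2	tm5_p3
hZIP9	L152	H155	A156	D159	H185	K186	A189	A190	L193
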