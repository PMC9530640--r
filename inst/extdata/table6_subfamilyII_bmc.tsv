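member	tm4_p3p	tm4_p1	tm4_p2	tm4_p3	tm5_p1p	tm5_p2p	tm5_p1	tm5_p2	tm5_p3
hZIP1	L187	H190	S191	E194	H217	K218	L221	A222	L225
hZIP2	L172	H175	S176	E179	H202	K203	V206	V207	V210
hZIP3	L177	H180	S181	E184	H207	E208	V211	A212	L215
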