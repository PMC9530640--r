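member	tm4_p3p	tm4_p1	tm4_p2	tm4_p3	tm5_p1p	tm5_p2p	tm5_p1	tm5_p2	tm5_p3
hZIP11	I201	H204	N205	E208	Q240	N241	E244	G245	V248
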