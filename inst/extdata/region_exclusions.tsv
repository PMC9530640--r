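member	exclude
hZIP3	109-166
hZIP4	1-300,402-468
hZIP9	79-99,268-284
hZIP11	102-187
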