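member	signal_peptide
hZIP1	Absent
hZIP2	Absent
hZIP3	Absent
hZIP4	1-22
hZIP5	1-24
hZIP6	1-28
hZIP7	1-27
hZIP8	1-22
hZIP9	Absent
hZIP10	1-25
hZIP11	Absent
hZIP12	1-23
hZIP13	1-32
hZIP14	1-30
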