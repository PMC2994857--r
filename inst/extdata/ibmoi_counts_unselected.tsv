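base	A	C	G	T
A	23656	18	27	182
C	65	18045	1	184
G	282	4	11176	29
T	270	29	19	15439
Total	24273	18096	11223	15834
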