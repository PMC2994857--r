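base	A	C	G	T
A	24024	11	12	80
C	24	18058	1	72
G	154	0	11203	9
T	71	27	7	15673
Total	24273	18096	11223	15834
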