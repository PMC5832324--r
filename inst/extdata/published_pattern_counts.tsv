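pattern	n
222	33
221	126
220	33
211	13
210	140
200	25
122	309
121	17
112	8
111	1777
110	18
101	42
100	377
022	36
012	36
011	8
002	9
001	120
000	85
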