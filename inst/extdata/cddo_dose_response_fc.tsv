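probe_id	C3	C10	C30
1417168_a_at	-1.43	12.84	1.00
1456225_x_at	1.25	6.49	1.41
1416432_at	-1.45	4.78	1.45
1451548_at	-1.14	3.91	-2.06
1452026_a_at	1.30	3.83	-1.01
1448667_x_at	1.67	3.56	1.77
1450703_at	1.09	3.53	1.45
1416773_at	-1.23	3.28	1.15
1445843_at	2.24	3.20	2.07
1449409_at	1.31	3.17	-1.78
1460521_a_at	1.20	3.07	1.91
1428730_at	2.54	2.92	1.92
1454617_at	1.08	2.89	-1.40
1451716_at	1.43	2.86	1.18
1421852_at	1.63	2.78	1.11
1436830_at	1.03	2.78	-1.15
1450743_s_at	1.80	2.74	2.31
1440146_at	1.19	2.72	1.39
1429432_at	1.76	2.63	2.01
1431098_at	2.01	2.63	2.16
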