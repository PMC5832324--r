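probe_id	gene_symbol
1417168_a_at	Usp2
1456225_x_at	Trib3
1416432_at	Pfkfb3
1451548_at	Upp2
1452026_a_at	Pla2g12a
1448667_x_at	Tob2
1450703_at	Slc7a2
1416773_at	Wee1
1445843_at	Chd2
1449409_at	Sult1c2
1460521_a_at	Obfc2a
1428730_at	Krit1
1454617_at	Arrdc3
1451716_at	Mafb
1421852_at	Kcnk5
1436830_at	Marveld1
1450743_s_at	Syncrip
1440146_at	Vps13a
1429432_at	Bat2d
1431098_at	Clip1
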