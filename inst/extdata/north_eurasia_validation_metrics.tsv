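class	precision	recall	f1	support
Amur_Nanais&Nivkhs&Orochi&Ulchi	1.00	1.00	1.00	12
Bashkirs	0.71	0.77	0.74	13
Buryats&Khamnegan&Yakuts	0.79	0.88	0.83	17
Chechens&Ingush	1.00	0.63	0.77	8
Chukchi&Koryaks&Itelmen	1.00	1.00	1.00	20
Dagestan	0.90	0.90	0.90	20
Evenks&Evens	1.00	1.00	1.00	14
Karelians&Veps	1.00	0.73	0.84	11
Kazakh&Karakalpak&Uigur&Nogais	0.75	0.30	0.43	10
Khakass&AltaiSouth	1.00	0.92	0.96	13
Khanty&Mansi&Nenets	0.94	1.00	0.97	16
Komi&Udmurts	0.96	0.88	0.92	25
Kyrghyz	0.83	0.50	0.63	10
Mari&Chuvash	0.84	1.00	0.91	16
Mongols&Kalmyks	0.82	0.95	0.88	38
Mordovians	0.80	0.67	0.73	12
Ossets	0.86	0.55	0.67	11
Russians_North	0.80	0.35	0.48	23
Russians_Southern	0.75	0.93	0.83	59
Russians_VeryNorth	1.00	0.90	0.95	10
Shors&AltaiNorth	1.00	1.00	1.00	10
Siberian Tatars	1.00	0.65	0.79	20
Tajiks&Pomiri&Yaghnobi	0.81	0.95	0.88	22
Tatars	0.60	0.38	0.46	16
Transcaucasia&Crimea	0.92	0.96	0.94	25
Tuvinians&Tofalars	1.00	1.00	1.00	17
Ukrainians	0.57	1.00	0.73	24
Uzbeks&Turkmens	0.86	0.86	0.86	14
West_Caucasus	0.75	0.81	0.78	26
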