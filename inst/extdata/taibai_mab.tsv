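# Mountain altitudinal belts of Taibai Mountain (Qinling Mountains, summit 3771.2 m).
# Half-open altitude intervals [alt_lo, alt_hi); top belt closed at the top.
slope	formation	alt_lo	alt_hi
north	Basal zone	0	800
north	Quercus variabilis forest	800	1000
north	Quercus aliena var. acuteserrata forest	1000	1900
north	Quercus liaotungensis forest	1900	2300
north	mixed forests of Betula albosinensis with Pinus armandii	2300	2700
north	Betula albosinensis var. septentrionalis forest	2700	2800
north	Abies fargesii forest	2800	3000
north	Larix chinensis forest	3000	3400
north	subalpine shrub and meadow	3400	3777
south	Basal zone	0	750
south	Quercus variabilis forest	750	1300
south	Quercus aliena var. acuteserrata forest	1300	2000
south	mixed forests of Betula albosinensis with Pinus armandii	2000	2300
south	mixed forests of Betula albosinensis with Betula albosinensis var. septentrionalis	2300	2650
south	Abies fargesii forest	2650	3000
south	Larix chinensis forest	3000	3400
south	subalpine shrub and meadow	3400	3777
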