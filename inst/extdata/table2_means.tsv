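variable	condition	mean
hindfoot_eversion	natural	1.1
hindfoot_eversion	functional	5.7
hindfoot_eversion	forced	7.1
hindfoot_eversion	saute	15.8
midfoot_abduction	natural	2.8
midfoot_abduction	functional	5.6
midfoot_abduction	forced	6.3
midfoot_abduction	saute	7.7
forefoot_abduction	natural	7.6
forefoot_abduction	functional	8.4
forefoot_abduction	forced	8.8
forefoot_abduction	saute	8.7
navicular_drop_mm	natural	0
navicular_drop_mm	functional	1.6
navicular_drop_mm	forced	1.9
navicular_drop_mm	saute	12.9
mtpj_abduction	natural	10.7
mtpj_abduction	functional	12.0
mtpj_abduction	forced	13.5
mtpj_abduction	saute	13.1
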