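variable	level	n_mpm	n_spm	is_ref
age_at_diagnosis	<=51	97	44	1
age_at_diagnosis	>51	80	49	0
sex	F	93	62	1
sex	M	84	31	0
eye_color	dark	81	30	1
eye_color	light	82	43	0
hair_color	blonde	61	27	1
hair_color	brown/black	83	44	0
hair_color	red	19	2	0
phototype	I-II	90	35	1
phototype	III-IV	73	38	0
sunburns	often	94	36	1
sunburns	rarely/never	67	36	0
nevi	<50	75	40	1
nevi	>50	77	22	0
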