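period	older_Ga	younger_Ga
Cenozoic	0.066	0
Mesozoic	0.252	0.066
Paleozoic	0.541	0.252
Neoproterozoic	1.0	0.541
Mesoproterozoic	1.6	1.0
Paleoproterozoic	2.5	1.6
Neoarchean	2.8	2.5
Mesoarchean	3.2	2.8
Paleoarchean	3.6	3.2
Eoarchean	4.0	3.6
Hadean	4.6	4.0
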