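population	country	sample_area	years	tissue	sampling_method	n	n_new
Fennoscandia	Sweden	Vindelfjallen	1989-2019	Ear tissue	Ear tagging	15	0
Fennoscandia	Sweden	Arjeplog	2008-2019	Ear tissue	Ear tagging	11	5
Fennoscandia	Norway	Saltfjellet	2007	Ear tissue	Ear tagging	1	0
Fennoscandia	Norway	Reisa nord	2007	Ear tissue	Ear tagging	1	0
Fennoscandia	Norway	Varangerhalvoya	2011	Muscle tissue	Injured fox	1	0
Fennoscandia	Norway	Ovre Dividal	2005	Ear tissue	Ear tagging	1	0
Fennoscandia	Russia	Kola	1990s	Muscle tissue	Carcass sampling	1	0
Siberia	Russia	Indigirka	1994	Muscle tissue	Carcass sampling	1	1
Siberia	Russia	Yamal	1994-2011	Skin/muscle tissue	Carcass sampling	4	0
Siberia	Russia	Taymyr	1994	Skin/muscle tissue	Carcass sampling	5	4
Siberia	Russia	Faddeyevsky Island	1994	Muscle tissue	Carcass sampling	1	1
Siberia	Russia	Wrangel Island	2008	Skin tissue	Carcass sampling	1	1
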