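soc	case_number	pt_count	percentage
General disorders and administration site conditions	15378	146	21.17
Gastrointestinal disorders	11442	246	15.75
Respiratory, thoracic and mediastinal disorders	6260	196	8.62
Skin and subcutaneous tissue disorders	5773	158	7.95
Nervous system disorders	5511	161	7.59
Investigations	5012	304	6.90
Metabolism and nutrition disorders	4362	63	6.01
Infections and infestations	4177	222	5.75
Injury, poisoning and procedural complications	3513	190	4.84
Psychiatric disorders	2366	107	3.26
Musculoskeletal and connective tissue disorders	1769	112	2.44
Cardiac disorders	1427	103	1.96
Vascular disorders	1048	75	1.44
Neoplasms benign, malignant and unspecified (incl cysts and polyps)	796	198	1.10
Surgical and medical procedures	671	99	0.92
Renal and urinary disorders	660	67	0.91
Eye disorders	591	75	0.81
Hepatobiliary disorders	447	51	0.62
Ear and labyrinth disorders	346	26	0.48
Blood and lymphatic system disorders	331	49	0.46
Immune system disorders	328	23	0.45
Social circumstances	158	27	0.22
Reproductive system and breast disorders	109	49	0.15
Product issues	79	30	0.11
Endocrine disorders	51	19	0.07
Congenital, familial and genetic disorders	18	11	0.02
Pregnancy, puerperium and perinatal conditions	3	2	0.00
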