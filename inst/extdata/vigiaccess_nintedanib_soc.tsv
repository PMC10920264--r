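soc	case_number	pt_count	percentage
Gastrointestinal disorders	13433	303	22.77
General disorders and administration site conditions	7425	172	12.59
Respiratory, thoracic and mediastinal disorders	6388	178	10.83
Investigations	6084	361	10.31
Nervous system disorders	3670	198	6.22
Metabolism and nutrition disorders	3577	84	6.06
Infections and infestations	3474	275	5.89
Musculoskeletal and connective tissue disorders	1908	125	3.23
Injury, poisoning and procedural complications	1886	217	3.20
Skin and subcutaneous tissue disorders	1501	136	2.54
Psychiatric disorders	1375	114	2.33
Cardiac disorders	1363	101	2.31
Vascular disorders	1360	94	2.31
Hepatobiliary disorders	1002	58	1.70
Neoplasms benign, malignant and unspecified (incl cysts and polyps)	995	170	1.69
Renal and urinary disorders	824	82	1.40
Surgical and medical procedures	734	174	1.24
Blood and lymphatic system disorders	694	65	1.18
Eye disorders	445	76	0.75
Immune system disorders	230	25	0.39
Ear and labyrinth disorders	220	26	0.37
Reproductive system and breast disorders	134	49	0.23
Social circumstances	130	32	0.22
Product issues	58	26	0.10
Endocrine disorders	48	11	0.08
Congenital, familial and genetic disorders	22	18	0.04
Pregnancy, puerperium and perinatal conditions	3	3	0.01
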