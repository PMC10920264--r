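soc	case_number	pt_count	percentage
Gastrointestinal disorders	8988	85	35.88
Respiratory, thoracic and mediastinal disorders	4384	65	17.50
General disorders and administration site conditions	2712	18	10.83
Investigations	1987	49	7.93
Metabolism and nutrition disorders	1467	14	5.86
Immune system disorders	950	4	3.79
Vascular disorders	891	28	3.56
Cardiac disorders	759	22	3.03
Nervous system disorders	548	16	2.19
Hepatobiliary disorders	465	19	1.86
Injury, poisoning and procedural complications	455	14	1.82
Surgical and medical procedures	322	24	1.29
Renal and urinary disorders	243	13	0.97
Infections and infestations	224	14	0.89
Neoplasms benign, malignant and unspecified (incl cysts and polyps)	200	8	0.80
Musculoskeletal and connective tissue disorders	201	6	0.80
Psychiatric disorders	100	5	0.40
Blood and lymphatic system disorders	66	6	0.26
Skin and subcutaneous tissue disorders	38	4	0.15
Eye disorders	26	2	0.10
Reproductive system and breast disorders	12	3	0.05
Social circumstances	9	2	0.04
Ear and labyrinth disorders	6	1	0.02
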