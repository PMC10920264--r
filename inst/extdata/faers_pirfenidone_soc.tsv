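soc	case_number	pt_count	percentage
Gastrointestinal disorders	9927	21	30.63
General disorders and administration site conditions	8009	8	24.71
Respiratory, thoracic and mediastinal disorders	4694	44	14.48
Metabolism and nutrition disorders	2168	7	6.69
Skin and subcutaneous tissue disorders	1969	9	6.08
Investigations	1925	21	5.94
Cardiac disorders	1343	6	4.14
Psychiatric disorders	759	5	2.34
Injury, poisoning and procedural complications	748	6	2.31
Nervous system disorders	406	4	1.25
Immune system disorders	228	2	0.70
Renal and urinary disorders	69	1	0.21
Vascular disorders	66	5	0.20
Surgical and medical procedures	66	5	0.20
Social circumstances	14	1	0.04
Musculoskeletal and connective tissue disorders	8	1	0.02
Reproductive system and breast disorders	6	2	0.02
Infections and infestations	3	1	0.01
Ear and labyrinth disorders	3	1	0.01
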