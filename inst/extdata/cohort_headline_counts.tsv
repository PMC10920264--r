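label	count	total	printed_pct
pirfenidone_over65_faers	16716	55949	29.88
nintedanib_over65_faers	20330	35884	56.65
pirfenidone_hospitalization_faers	10869	55949	19.43
nintedanib_hospitalization_faers	17433	35884	48.58
pirfenidone_over65_vigiaccess	14409	37187	38.75
nintedanib_over65_vigiaccess	13245	23134	57.25
pirfenidone_age_missing_faers	20047	37187	53.91
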