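source_id	definition_column	classification	hierarchical	ignore_case	date_rule	default_event_flag	min_instances	code_map	field_id	timing_field	timing_type
hesin_icd10	ICD10	icd10	TRUE	FALSE	record	1	1	icd10.tsv			
hesin_icd9	ICD9	icd9	TRUE	FALSE	record	1	1	icd9.tsv			
hesin_oper	OPCS4	opcs4	TRUE	FALSE	record	1	1	opcs4.tsv			
gpclinical.read2	READ2	read2	TRUE	FALSE	record	1	1	read2.tsv			
gpclinical.read3	CTV3	read3	TRUE	FALSE	record	1	1	ctv3.tsv			
gpscripts	DMD	dmd	FALSE	FALSE	record	1	1	dmd.tsv			
tte.death.icd10.primary	ICD10	icd10	TRUE	FALSE	record	1	1	icd10.tsv			
tte.death.icd10.secondary	ICD10	icd10	TRUE	FALSE	record	1	1	icd10.tsv			
sr_20001	SR	sr	FALSE	FALSE	timing	2	1		20001	20006	year
sr_20002	SR	sr	FALSE	FALSE	timing	2	1		20002	20008	year
sr_20003	SR	sr	FALSE	FALSE	visit	0	1		20003		
sr_20004	SR	sr	FALSE	FALSE	timing	1	1		20004	20010	year
ts	TS	ts	FALSE	FALSE	condition	0	1				
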