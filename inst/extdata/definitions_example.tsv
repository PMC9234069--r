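TRAIT	DESCRIPTION	ICD10	ICD9	OPCS4	READ2	CTV3	DMD	SR	TS	Study_population	Include_definitions	Exclude_from_cases	Exclude_from_controls
DmT2	Type 2 diabetes (specific codes)	E11	25000, 25002		C10F.	X40J5, XaELQ		20002(1223)					
DmT1	Type 1 diabetes (specific codes)	E10				X40J6		20002(1222)					
DmG	Gestational diabetes	O24						20002(1221)	4041=1[2976](Gestational diabetes)				
Dm	Any diabetes diagnosis code	E10, E11, O24	250		C10..	X40J5, X40J6, XaELQ, C1001		20002(1220, 1221, 1222, 1223)	2443=1[2976]				
RxDmOr	Oral antidiabetic medication						met00001(metformin), sulf0001	20003(1140884600)					
RxDmIns	Insulin use						ins00001	20003(1140883066)	6177=3(insulin)				
RxDm	Any antidiabetic medication										RxDmOr, RxDmIns		
RxMet	Metformin use						met00001	20003(1140884600)					
DmRxT2	Type 2 diabetes incl. oral medication	E11	25000, 25002		C10F.	X40J5, XaELQ		20002(1223)			RxDmOr	DmT1	RxDm
Af	Atrial fibrillation or flutter	I48	4273	K62	G573.	G573., XaEga, X202R		20002(1471, 1483)					
Hf	Heart failure	I50, I110	428	K02	G58..	XE2QG, X202k		20002(1076), 20004(1098)					
HfInDm	Heart failure within diabetes	I50, I110	428		G58..	XE2QG, X202k		20002(1076)		Dm			
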