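E10	Insulin-dependent diabetes mellitus
E100	Type 1 diabetes with coma
E101	Type 1 diabetes with ketoacidosis
E109	Type 1 diabetes without complications
E11	Non-insulin-dependent diabetes mellitus
E110	Type 2 diabetes with coma
E119	Type 2 diabetes without complications
O24	Diabetes mellitus in pregnancy
O244	Gestational diabetes mellitus
I48	Atrial fibrillation and flutter
I480	Paroxysmal atrial fibrillation
I481	Persistent atrial fibrillation
I489	Atrial fibrillation and flutter, unspecified
I50	Heart failure
I500	Congestive heart failure
I501	Left ventricular failure
I509	Heart failure, unspecified
I110	Hypertensive heart disease with heart failure
I10	Essential (primary) hypertension
I21	Acute myocardial infarction
I210	AMI anterior wall
I219	AMI unspecified
I25	Chronic ischaemic heart disease
I251	Atherosclerotic heart disease
I252	Old myocardial infarction
E78	Disorders of lipoprotein metabolism
E780	Pure hypercholesterolaemia
J45	Asthma
J450	Predominantly allergic asthma
K21	Gastro-oesophageal reflux disease
M54	Dorsalgia
R99	Ill-defined and unknown cause of mortality
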