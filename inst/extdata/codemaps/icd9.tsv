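250	Diabetes mellitus
25000	Type 2 diabetes without complication
25002	Type 2 diabetes uncontrolled
4273	Atrial fibrillation and flutter
428	Heart failure
4280	Congestive heart failure
410	Acute myocardial infarction
4109	AMI unspecified
401	Essential hypertension
4019	Hypertension unspecified
272	Disorders of lipoid metabolism
2724	Hyperlipidemia
493	Asthma
5309	Oesophageal disorder
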