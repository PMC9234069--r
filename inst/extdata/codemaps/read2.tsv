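C10..	Diabetes mellitus
C100.	Diabetes mellitus type distinction
C1001	Diabetes mellitus with no complication
C10F.	Type 2 diabetes mellitus
C10F9	Type 2 diabetes without complication
C10FJ	Insulin treated type 2 diabetes
G573.	Atrial fibrillation and flutter
G5730	Atrial fibrillation
G5731	Atrial flutter
G573z	Atrial fibrillation and flutter NOS
G58..	Heart failure
G5800	Acute congestive heart failure
G5810	Acute left ventricular failure
H33..	Asthma
H330.	Extrinsic asthma
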