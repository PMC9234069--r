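X40J5	Type 2 diabetes mellitus
X40J6	Type 1 diabetes mellitus
XaELQ	Diabetes mellitus type 2 review
C1001	Diabetes mellitus with no complication
G573.	Atrial fibrillation and flutter
G5730	Atrial fibrillation
XaEga	Atrial fibrillation monitoring
X202R	Paroxysmal atrial fibrillation
XE2QG	Heart failure
X202k	Chronic heart failure
XE0Yw	Asthma monitoring
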