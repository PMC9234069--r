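met00001	Metformin 500mg tablets
sulf0001	Gliclazide 80mg tablets
ins00001	Insulin glargine 100units/ml
stat0001	Simvastatin 40mg tablets
amlo0001	Amlodipine 5mg tablets
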