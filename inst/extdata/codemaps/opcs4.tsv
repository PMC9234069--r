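K40	Saphenous vein graft replacement of coronary artery
K401	Autograft replacement of one coronary artery
K49	Transluminal balloon angioplasty of coronary artery
K491	Percutaneous balloon coronary angioplasty
K62	Therapeutic transluminal operations on heart
K621	Percutaneous ablation for atrial fibrillation
K622	Percutaneous ablation for atrial flutter
K623	Percutaneous ablation of conducting system of heart
K02	Transplantation of heart
W37	Total prosthetic replacement of hip joint
W371	Primary total hip replacement
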