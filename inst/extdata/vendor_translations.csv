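vendor_name,shorthand_name
CholEster,CE
ChE,CE
TAG,TG
DAG,DG
MAG,MG
Cholesterol,Chol
FC,Chol
FFA,FA
AcCa,CAR
LysoPC,LPC
LysoPE,LPE
PlsEtn,PE P
PlsCho,PC P
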