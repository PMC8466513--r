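name,recognition,cut_offset
MluCI,AATT,0
Tsp509I,AATT,0
EcoRI,GAATTC,1
HinfI,GANTC,2
DdeI,CTNAG,1
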