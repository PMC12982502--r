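state,hectares
IA,5260000
IL,4410000
NE,3970000
MN,3240000
IN,2140000
WI,1580000
ND,1500000
MO,1420000
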