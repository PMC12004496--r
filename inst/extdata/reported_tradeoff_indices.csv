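grassland,litter,index
fenced,T0,0.0086
fenced,T1,0.0414
fenced,T2,0.0269
fenced,T3,0.0012
light,T0,0.0097
light,T1,0.002
light,T2,0.0494
light,T3,0.0140
moderate,T0,0.0005
moderate,T1,0.0307
moderate,T2,0.0196
moderate,T3,0.0383
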