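grassland,litter,variable,value,unit
fenced,T3,agb,213.35,g_m2
light,T3,agb,124.01,g_m2
moderate,T3,agb,102.54,g_m2
fenced,T3,rb,118.52,g_m2
light,T3,rb,138.51,g_m2
moderate,T3,rb,98.4,g_m2
fenced,T3,apc,368.43,mg_g
light,T3,apc,407.07,mg_g
moderate,T3,apc,412.94,mg_g
fenced,T3,rc,300.05,mg_g
light,T3,rc,249.23,mg_g
moderate,T3,rc,270.77,mg_g
fenced,T3,apcp,78.57,g_m2
light,T3,apcp,50.56,g_m2
moderate,T3,apcp,42.33,g_m2
fenced,T3,rcp,35.66,g_m2
light,T3,rcp,34.52,g_m2
moderate,T3,rcp,26.23,g_m2
fenced,T3,tpcp,114.23,g_m2
light,T3,tpcp,85.08,g_m2
moderate,T3,tpcp,68.95,g_m2
fenced,T2,mbc,1005.14,mg_kg
light,T3,mbc,889.68,mg_kg
moderate,T3,mbc,966.02,mg_kg
fenced,T2,mbcp,0.20,g_m2
light,T3,mbcp,0.28,g_m2
moderate,T3,mbcp,0.32,g_m2
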