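name,lifespan_d,density_kg_m3,demand_g_capita_d,production_ratio,m1,m2,m3,m4,m5,m6,m7,m8,m9,m10,m11,m12,cold_factor
potato,21,650,90,0.4,4,4,4,0,0,0,0,0,0,0,0,0,0.25
onion,15,550,45,1.2,0,0,4,4,4,0,0,0,0,0,0,0,0.25
tomato,6,600,45,1.5,1.5,1.5,1,1,0.5,0.5,0.5,0.5,1,1,1.5,1.5,0.4
brinjal,4,350,50,5.2,1,1,1,1,1,1,1,1,1,1,1,1,0.4
cabbage,7,400,36,1.2,2,2,1.5,1,0.5,0.25,0.25,0.25,0.5,1,1.5,2,0.4
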