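taxon,alpha_m,nest_ground,nest_cavity,nest_wood,activity_spring,activity_summer
Bombus,1500,0.5,1,0.25,0.4,0.6
Melissodes,800,1,0,0,0.1,0.9
Megachile,600,0.25,1,0.75,0.3,0.7
Osmia,600,0.25,1,0.75,0.8,0.2
Andrena,500,1,0,0,0.7,0.3
Agapostemon,500,1,0,0,0.3,0.7
Halictus,400,1,0,0,0.4,0.6
Ceratina,300,0,0.5,1,0.4,0.6
Hylaeus,200,0,1,0.75,0.3,0.7
Lasioglossum,100,1,0.25,0,0.4,0.6
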