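class_id,name,is_natural,is_agricultural,is_cultivated,nest_ground,nest_cavity,nest_wood,floral_spring,floral_summer
1,crop_low_floral,FALSE,TRUE,TRUE,0.25,0,0,0.25,0.25
2,crop_floral,FALSE,TRUE,TRUE,0.25,0,0,0.5,0.5
3,ag_noncultivated,FALSE,TRUE,FALSE,0.5,0.25,0,0.5,0.5
4,forest,TRUE,FALSE,FALSE,0.5,1,1,0.75,0.25
5,wetland,TRUE,FALSE,FALSE,0.25,0.5,0.25,0.5,0.5
6,oldfield_shrubland,TRUE,FALSE,FALSE,0.75,0.5,0.5,0.75,0.75
7,urban_vegetation,FALSE,FALSE,FALSE,0.5,0.25,0.25,0.5,0.5
8,impervious,FALSE,FALSE,FALSE,0,0,0,0,0
9,water,FALSE,FALSE,FALSE,0,0,0,0,0
10,bare_ground,FALSE,FALSE,FALSE,0.25,0,0,0,0
11,flower_strip,TRUE,FALSE,FALSE,0.5,0,0,1,1
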