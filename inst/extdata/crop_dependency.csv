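crop_code,dependency_class,weight
corn,none,0
soybean,little,0.05
wheat,none,0
hay,none,0
vegetables,modest,0.25
canola,great,0.65
berries,great,0.65
orchard,essential,0.95
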