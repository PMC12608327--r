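dominant_species,diff_class,area_ha
Birch,-5,3.66
Birch,-3,2.23
Birch,-2,1.16
Birch,0,1.05
Alder,-5,2.74
Alder,-4,1.03
Alder,-3,5.94
Alder,-2,2.34
Alder,-1,1.69
Alder,0,2.34
Alder,1,1.86
Larch,-3,0.99
Spruce,-3,2.96
Spruce,-2,2.36
Spruce,6,0.65
Pine,-5,1.12
Pine,-3,8.6
Pine,-2,109.34
Pine,-1,248.36
Pine,0,332.38
Pine,1,265.03
Pine,2,63.29
Pine,3,20.68
Pine,4,10.84
Pine,5,0.26
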