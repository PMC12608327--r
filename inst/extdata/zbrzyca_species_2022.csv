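dominant_species,diff_class,area_ha
Birch,"[-8,-6]",5.92
Birch,-2,1.22
Birch,0,1.05
Alder,"[-8,-6]",6.99
Alder,-5,3.42
Alder,-4,2.83
Alder,-3,2.88
Alder,-2,2.19
Larch,-5,0.99
Larch,4,0.5
Spruce,"[-8,-6]",2.36
Spruce,-2,0.6
Spruce,3,0.72
Pine,"[-8,-6]",0.83
Pine,-5,2.89
Pine,-4,0.45
Pine,-2,61.34
Pine,-1,108.09
Pine,0,268.39
Pine,1,314.56
Pine,2,199.45
Pine,3,48.01
Pine,4,13.23
Pine,5,2.5
Pine,6,6.87
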