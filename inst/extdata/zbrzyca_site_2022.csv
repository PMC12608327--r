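site_type,diff_class,area_ha
FPF,-4,0.45
FPF,-2,51.91
FPF,-1,61.87
FPF,0,186.03
FPF,1,179.34
FPF,2,80.04
FPF,3,18.54
FPF,5,1.76
FPF,6,2.91
BMF,-1,0.55
BMF,0,0.99
MMCF,-5,0.77
MMCF,-2,0.76
MMCF,1,1.23
FMCF,-2,8.67
FMCF,-1,40.59
FMCF,0,72.51
FMCF,1,130.92
FMCF,2,116.6
FMCF,3,28.25
FMCF,4,12.93
FMCF,5,0.74
FMCF,6,3.87
FMHF,"[-8,-6]",3.81
FMHF,-5,3.11
FMHF,-2,1.82
FMHF,-1,5.08
FMHF,0,9.91
FMHF,1,3.07
FMHF,2,2.81
FMHF,3,1.94
FMHF,4,0.8
MMF,-3,0.54
TASF,"[-8,-6]",11.08
TASF,-5,3.42
TASF,-4,2.83
TASF,-3,2.34
TASF,-2,2.19
AAF,"[-8,-6]",1.21
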