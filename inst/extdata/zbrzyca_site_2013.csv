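site_type,diff_class,area_ha
FPF,-3,1.45
FPF,-2,85.3
FPF,-1,194.08
FPF,0,204.45
FPF,1,129.91
FPF,2,9.26
FPF,3,1.74
BMF,-1,0.55
BMF,0,0.92
MMCF,-1,1.94
FMCF,-3,2.59
FMCF,-2,22.23
FMCF,-1,49.46
FMCF,0,122.27
FMCF,1,123.51
FMCF,2,52.87
FMCF,3,17.72
FMCF,4,10.04
FMHF,-5,1.12
FMHF,-3,6.18
FMHF,-2,5.93
FMHF,-1,2.33
FMHF,0,5.79
FMHF,1,11.61
FMHF,2,1.16
FMHF,3,1.22
FMHF,4,0.8
FMHF,5,0.26
FMHF,6,0.65
MMF,-2,0.54
TASF,-5,5.19
TASF,-4,1.03
TASF,-3,7.54
TASF,-2,1.8
TASF,-1,1.69
TASF,0,2.34
TASF,1,1.86
AAF,-5,1.21
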