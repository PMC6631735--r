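label,variant,nutrient,value
MTL,mean,energy,-6.36
MTL,mean,fats,-17.59
MTL,mean,sfa,-24.01
MTL,mean,salt,-5.39
MTL,mean,fibre,0.86
MTL,mean,fruit,-4.08
MTL,mean,vegetable,-0.87
HSR,mean,energy,-4.77
HSR,mean,fats,-14.63
HSR,mean,sfa,-19.83
HSR,mean,salt,-7.1
HSR,mean,fibre,10.77
HSR,mean,fruit,6.19
HSR,mean,vegetable,2.81
RIs,mean,energy,-2.99
RIs,mean,fats,-9.1
RIs,mean,sfa,-14.17
RIs,mean,salt,-3.41
RIs,mean,fibre,2.41
RIs,mean,fruit,10.14
RIs,mean,vegetable,4.89
NutriScore,mean,energy,-9.04
NutriScore,mean,fats,-21.38
NutriScore,mean,sfa,-29.89
NutriScore,mean,salt,-4.1
NutriScore,mean,fibre,7.21
NutriScore,mean,fruit,12.36
NutriScore,mean,vegetable,5.38
SENS,mean,energy,-2.39
SENS,mean,fats,-9.59
SENS,mean,sfa,-11.1
SENS,mean,salt,1.29
SENS,mean,fibre,9.71
SENS,mean,fruit,-0.01
SENS,mean,vegetable,1.7
Control,mean,energy,-0.7
Control,mean,fats,0.75
Control,mean,sfa,1.63
Control,mean,salt,3.29
Control,mean,fibre,-0.99
Control,mean,fruit,3.67
Control,mean,vegetable,3.54
MTL,best_case,energy,-9.09
MTL,best_case,fats,-22.7
MTL,best_case,sfa,-31.68
MTL,best_case,salt,-6.86
MTL,best_case,fibre,3.36
MTL,best_case,fruit,-5.87
MTL,best_case,vegetable,1.12
HSR,best_case,energy,-6.4
HSR,best_case,fats,-23.66
HSR,best_case,sfa,-30.69
HSR,best_case,salt,-11.54
HSR,best_case,fibre,17.36
HSR,best_case,fruit,22.1
HSR,best_case,vegetable,7
RIs,best_case,energy,-5.31
RIs,best_case,fats,-20.37
RIs,best_case,sfa,-28.4
RIs,best_case,salt,-10.19
RIs,best_case,fibre,4.23
RIs,best_case,fruit,4.27
RIs,best_case,vegetable,15.19
NutriScore,best_case,energy,-13.42
NutriScore,best_case,fats,-27
NutriScore,best_case,sfa,-41.19
NutriScore,best_case,salt,-6.88
NutriScore,best_case,fibre,11.21
NutriScore,best_case,fruit,11.93
NutriScore,best_case,vegetable,10.98
SENS,best_case,energy,-6.99
SENS,best_case,fats,-24.31
SENS,best_case,sfa,-21.83
SENS,best_case,salt,-3.45
SENS,best_case,fibre,9.16
SENS,best_case,fruit,-1.52
SENS,best_case,vegetable,3.55
Control,best_case,energy,-2.32
Control,best_case,fats,-6.77
Control,best_case,sfa,-7.97
Control,best_case,salt,2.02
Control,best_case,fibre,2.36
Control,best_case,fruit,9.99
Control,best_case,vegetable,10.18
MTL,worst_case,energy,-2.82
MTL,worst_case,fats,-13.12
MTL,worst_case,sfa,-14.78
MTL,worst_case,salt,-2.45
MTL,worst_case,fibre,-5.49
MTL,worst_case,fruit,-15.25
MTL,worst_case,vegetable,-6.05
HSR,worst_case,energy,-1.04
HSR,worst_case,fats,-0.33
HSR,worst_case,sfa,-2.1
HSR,worst_case,salt,-1.02
HSR,worst_case,fibre,-1.11
HSR,worst_case,fruit,-9.85
HSR,worst_case,vegetable,-0.7
RIs,worst_case,energy,0.64
RIs,worst_case,fats,2.58
RIs,worst_case,sfa,-4.75
RIs,worst_case,salt,5.22
RIs,worst_case,fibre,0.64
RIs,worst_case,fruit,5.3
RIs,worst_case,vegetable,-5.41
NutriScore,worst_case,energy,-7.16
NutriScore,worst_case,fats,-10.75
NutriScore,worst_case,sfa,-12.98
NutriScore,worst_case,salt,-2.32
NutriScore,worst_case,fibre,-4.83
NutriScore,worst_case,fruit,0.14
NutriScore,worst_case,vegetable,-3.14
SENS,worst_case,energy,2.24
SENS,worst_case,fats,2.79
SENS,worst_case,sfa,2.98
SENS,worst_case,salt,5.34
SENS,worst_case,fibre,6.44
SENS,worst_case,fruit,-3.34
SENS,worst_case,vegetable,-6.24
Control,worst_case,energy,7.19
Control,worst_case,fats,18.77
Control,worst_case,sfa,26.15
Control,worst_case,salt,14.73
Control,worst_case,fibre,-3.78
Control,worst_case,fruit,1.3
Control,worst_case,vegetable,3.8
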