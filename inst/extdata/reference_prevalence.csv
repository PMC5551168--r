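label,outcome,prevalence,ci_lower,ci_upper
synthetic_microdata,exercise,64.9,62.5,67.2
synthetic_microdata,fruitveg,17.9,15.4,20.7
synthetic_microdata,diabetes,11.1,9.8,12.4
city_brfss,exercise,66.3,64.4,68.2
city_brfss,fruitveg,20.6,18.2,22.9
city_brfss,diabetes,10.3,9.3,11.4
state_brfss,exercise,78.2,77.8,78.6
state_brfss,fruitveg,27.5,26.8,28.1
state_brfss,diabetes,7.4,7.2,7.6
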