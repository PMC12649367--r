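name,density,sos,b_over_a,delta_0.5MHz,delta_1MHz,delta_2MHz,delta_4MHz,delta_5MHz,gel_alpha
gel,1020,1580,7,0.005595,0.001399,0.00035,8.74e-05,5.59e-05,7
skin,1131,1655,7.2,0.0046541,0.0026709,0.001542,0.000897,0.000446,NA
cortical_bone,1862,3194,13,0.16803,0.083521,0.043824,0.022381,0.011284,NA
trabecular_bone,572,2325,80.6,0.016534,0.012361,0.0094581,0.0075485,0.0071822,NA
brain,1035,1550,7.3,0.00337525,0.0017176,0.0008808,0.0004524,0.0003635,NA
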