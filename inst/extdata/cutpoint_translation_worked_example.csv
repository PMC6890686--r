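block,category,sed,light_upper,mod_upper,ref_mean,ref_sd,comp_mean,comp_sd,lccc,diff,ci_lo,ci_hi,mape
translation,sedentary,45,NA,NA,769,69,744,71,0.86,-25,-55,6,3.25
translation,sedentary,50,NA,NA,769,69,766,69,0.92,-3,-33,27,0.39
translation,sedentary,55,NA,NA,769,69,786,67,0.90,17,-13,46,2.21
translation,light,45,100,NA,147,29,161,34,0.84,14,0,28,9.52
translation,light,45,105,NA,147,29,170,37,0.73,23,9,37,15.65
translation,light,45,110,NA,147,29,179,38,0.63,31,17,46,21.09
translation,light,50,100,NA,147,29,139,30,0.91,-8,-21,5,5.44
translation,light,50,105,NA,147,29,148,33,0.93,1,-12,15,0.68
translation,light,50,110,NA,147,29,157,34,0.89,9,-4,23,6.12
translation,light,55,100,NA,147,29,120,27,0.62,-27,-40,-15,18.37
translation,light,55,105,NA,147,29,129,29,0.78,-19,-31,-6,12.93
translation,light,55,110,NA,147,29,137,31,0.88,-10,-23,3,6.80
translation,moderate,NA,100,430,104,28,120,30,0.72,16,3,28,15.38
translation,moderate,NA,100,435,104,28,120,30,0.72,14,0,28,13.46
translation,moderate,NA,100,440,104,28,120,30,0.72,16,4,29,15.38
translation,moderate,NA,105,430,104,28,111,28,0.82,7,-5,19,6.73
translation,moderate,NA,105,435,104,28,111,28,0.81,7,-5,19,6.73
translation,moderate,NA,105,440,104,28,111,28,0.81,7,-5,19,6.73
translation,moderate,NA,110,430,104,28,103,26,0.84,-1,-13,10,0.96
translation,moderate,NA,110,435,104,28,103,26,0.84,-1,-13,11,0.96
translation,moderate,NA,110,440,104,28,103,26,0.84,-1,-13,11,0.96
translation,vigorous,NA,NA,430,9,7,9,7,0.95,0,-3,3,0
translation,vigorous,NA,NA,435,9,7,9,7,0.95,0,-3,3,0
translation,vigorous,NA,NA,440,9,7,9,7,0.95,0,-3,3,0
cross_validation,sedentary,50,110,440,750,78,755,94,0.85,5,-36,45,0.67
cross_validation,light,50,110,440,134,34,133,36,0.89,-2,-18,15,1.49
cross_validation,moderate,50,110,440,103,44,97,44,0.92,-6,-26,15,5.82
cross_validation,vigorous,50,110,440,7,7,7,7,0.90,1,-2,4,14.29
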