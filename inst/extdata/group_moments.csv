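group,n,ei_mean,ei_sd,ca_mean,ca_sd,sa_mean,sa_sd,age_mean,age_sd,n_male,n_female
HC,19,0.25,0.02,112,8.05,75.7,13.1,72.3,5.38,11,8
PD,19,0.29,0.05,105,20.0,67.0,18.8,73.6,5.74,11,8
AD,19,0.30,0.06,104,20.3,70.5,11.9,73.8,5.60,11,8
NPH,19,0.38,0.08,58.3,15.6,25,9.74,73.7,6.36,11,8
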