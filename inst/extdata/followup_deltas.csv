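arm,n,ei_mean,ei_sd,ca_mean,ca_sd,sa_mean,sa_sd
shunt,6,-0.03,0.02,13.2,14.3,13.1,6.7
no_shunt,5,0.00,0.01,-2.1,2.0,0.2,5.2
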