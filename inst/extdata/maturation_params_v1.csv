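# Synthetic stage-attainment parameters, version 1.
# tau_A..tau_H: mean age (years) at which each Demirjian stage is first
# reached, per sex and tooth (FDI 31-37). Empty tau cells: stage is
# completed before age 2, so a 2-18 y cohort is never observed below
# the tooth's first defined stage. Spacing follows a fast-early,
# slow-late power curve. field: developmental field of the tooth;
# subjects belong to one of two developmental profiles (probability
# lag_prob of a posterior-delayed profile in which the posterior field
# lags the anterior field by lag_years). offset_sd: shared
# between-subject tempo sd (years); jitter_sd: per-tooth within-subject
# sd (years). All values are synthetic calibration constants, not
# published population parameters.
sex,tooth,tau_A,tau_B,tau_C,tau_D,tau_E,tau_F,tau_G,tau_H,field,offset_sd,jitter_sd,lag_years,lag_prob
male,31,,,1.000,1.609,2.847,4.533,6.598,9.000,anterior,0.20,0.25,3.50,0.50
male,32,,,1.200,1.870,3.231,5.086,7.358,10.000,anterior,0.20,0.25,3.50,0.50
male,33,,,,2.200,3.375,5.763,9.016,13.000,anterior,0.20,0.25,3.50,0.50
male,34,2.100,2.598,3.609,4.987,6.675,8.638,10.852,13.300,posterior,0.20,0.25,3.50,0.50
male,35,2.500,3.029,4.103,5.567,7.361,9.446,11.799,14.400,posterior,0.20,0.25,3.50,0.50
male,36,,,,1.000,2.045,4.167,7.059,10.600,posterior,0.20,0.25,3.50,0.50
male,37,3.000,3.591,4.792,6.428,8.432,10.763,13.393,16.300,posterior,0.20,0.25,3.50,0.50
female,31,,,0.650,1.259,2.497,4.183,6.248,8.650,anterior,0.20,0.25,3.50,0.50
female,32,,,,0.850,1.801,4.104,6.753,9.650,anterior,0.20,0.25,3.50,0.50
female,33,,,,1.850,3.025,5.413,8.666,12.650,anterior,0.20,0.25,3.50,0.50
female,34,1.750,2.248,3.259,4.637,6.325,8.288,10.502,12.950,posterior,0.20,0.25,3.50,0.50
female,35,2.150,2.679,3.753,5.217,7.011,9.096,11.449,14.050,posterior,0.20,0.25,3.50,0.50
female,36,,,,0.650,1.695,3.817,6.709,10.250,posterior,0.20,0.25,3.50,0.50
female,37,2.650,3.241,4.442,6.078,8.082,10.413,13.043,15.950,posterior,0.20,0.25,3.50,0.50
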