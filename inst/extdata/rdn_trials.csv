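trial_id,label,order,year,n_active,n_sham,md,se_md,planned_n_active,planned_n_sham,planned_power,anticipated_delta,anticipated_sd,allocation_ratio,prospectively_powered
symplicity_htn3,SYMPLICITY HTN-3,1,2014,364,171,-1.96,1.54,316,158,0.95,-5,25,2,TRUE
desch_2015,Desch et al.,2,2015,35,36,-3.50,2.55,29,29,0.80,-6,8,1,TRUE
reset,ReSET,3,2016,36,33,-1.10,3.53,28,28,0.80,-10,13,1,TRUE
spyral_off_med,SPYRAL HTN-OFF MED,4,2017,38,42,-5.00,2.51,,,,,,1,FALSE
spyral_on_med,SPYRAL HTN-ON MED,5,2018,38,42,-7.40,2.63,,,,,,1,FALSE
radiance_solo,RADIANCE-HTN SOLO,6,2018,74,72,-1.60,2.04,64,64,0.80,-6,12,1,TRUE
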