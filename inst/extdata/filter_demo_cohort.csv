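"subject_id","hiv_status","visit_time","age_at_visit","aud_r_500","aud_r_1000","aud_r_2000","aud_r_4000","aud_l_500","aud_l_1000","aud_l_2000","aud_l_4000","tymp_type","tymp_pressure","tymp_admittance","hx_ear_drainage","hx_concussion","hx_noise_chemical","hx_neuro_disease","hx_mental_illness","hx_ototoxic","hx_chemotherapy"
"F1","positive",0,35,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"F1","positive",182,35.498288843258,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"F1","positive",364,35.9965776865161,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"F1","positive",1300,38.5592060232717,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"F2","positive",0,35,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"F2","positive",182,35.498288843258,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"F2","positive",364,35.9965776865161,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"F3","negative",0,35,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"F3","negative",182,35.498288843258,10,10,30,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"F3","negative",364,35.9965776865161,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"F3","negative",546,36.4948665297741,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"F4","positive",0,35,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE
"F4","positive",182,35.498288843258,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE
"F4","positive",364,35.9965776865161,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE
"F4","positive",546,36.4948665297741,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE
"F5","negative",0,35,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"F5","negative",180,35.4928131416838,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"F5","negative",370,36.0130047912389,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"F5","negative",550,36.5058179329227,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"F6","positive",0,35,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"F6","positive",185,35.5065023956194,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"F6","positive",360,35.9856262833676,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"F6","positive",545,36.492128678987,10,10,10,10,8,8,12,12,"A",-20,0.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
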