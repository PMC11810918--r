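cluster,n,bai_mean,bai_sd,phq9_mean,phq9_sd,pclc_mean,pclc_sd,pa_none_minimal,pa_low_moderate,pa_moderate_extreme,sa_none_minimal,sa_low_moderate,sa_moderate_extreme,age_mean,age_sd,male_n,education_mean,education_sd,undetectable_vl_n
C1,76,7.76,7.46,5.09,4.19,37.14,8.80,55,10,11,44,11,21,42.92,9.54,28,6.00,3.62,67
C2,32,5.03,1.91,2.34,2.22,20.81,1.67,28,3,1,27,5,0,49.59,8.08,13,6.47,3.94,30
C3,130,1.15,1.54,1.08,1.60,21.52,3.1,114,9,7,105,15,10,44.04,8.49,65,6.03,3.71,124
C4,39,0,0,0.05,0.22,17.1,0.31,33,4,2,32,2,5,41.74,6.86,21,6.97,3.49,38
total,277,3.25,5.12,2.18,3.17,25.10,9.11,230,26,21,208,33,36,44.05,8.77,127,6.21,3.68,259
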