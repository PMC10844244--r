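outcome,rr,ui_no_gamma_lower,ui_no_gamma_upper,ui_with_gamma_lower,ui_with_gamma_upper,bprf,ros,stars,pub_bias,n_studies,selected_covariates
stroke,1.46,1.28,1.68,1.11,1.93,1.16,0.07,2,no,3,
esophageal_cancer,2.14,1.77,2.57,0.89,5.15,1.02,0.01,2,no,22,maximally_adjusted; adjusted_smoking_age_sex
lip_oral_cavity_cancer,3.64,3.00,4.41,0.66,19.95,0.87,-0.07,1,no,70,specific_product; subpopulation
larynx_cancer,2.66,1.98,3.57,0.52,13.63,0.68,-0.20,1,no,24,aggregate_outcome; adjusted_age_sex
nasopharynx_cancer,2.50,1.79,3.49,0.49,12.66,0.64,-0.22,1,no,17,maximally_adjusted; adjusted_age_sex
other_pharynx_cancer,2.33,1.80,3.01,0.45,12.04,0.59,-0.27,1,no,31,aggregate_outcome; adjusted_age_sex
ischemic_heart_disease,1.30,0.88,1.92,0.29,5.83,NA,NA,0,no,8,
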