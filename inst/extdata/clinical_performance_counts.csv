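disorder,method,tp,fp,fn,tn
alpha_thalassemia,HPLC-HRMS,44,60,20,239
alpha_thalassemia,Sebia-CE,44,40,20,259
beta_thalassemia,HPLC-HRMS,39,31,1,268
beta_thalassemia,Sebia-CE,16,33,24,266
alpha_and_beta_thalassemia,HPLC-HRMS,2,0,0,299
alpha_and_beta_thalassemia,Sebia-CE,0,0,2,299
abnormal_hb,HPLC-HRMS,2,0,0,299
abnormal_hb,Sebia-CE,2,3,0,296
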