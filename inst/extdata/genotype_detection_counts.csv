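disorder,genotype,total,detected_hplc_hrms,detected_sebia_ce
alpha_thalassemia,overall,64,44,44
alpha_thalassemia,aa/--SEA,27,27,20
alpha_thalassemia,aa/-a3.7,19,7,14
alpha_thalassemia,aa/-a4.2,3,2,2
alpha_thalassemia,aa/aWSa,1,1,0
alpha_thalassemia,aa/aCSa,5,1,4
alpha_thalassemia,-a3.7/-a3.7,2,0,2
alpha_thalassemia,aaa_anti3.7/aa,2,2,0
alpha_thalassemia,aaa_anti4.2/aa,4,3,2
alpha_thalassemia,aaa_anti3.7/--SEA,1,1,0
beta_thalassemia,overall,40,39,16
beta_thalassemia,bN/bCodon17,13,13,5
beta_thalassemia,bN/bIVS-II-654,13,13,5
beta_thalassemia,bN/bCodons41-42,11,10,6
beta_thalassemia,bN/bCodons27-28,1,1,0
beta_thalassemia,bN/bCodons71-72,1,1,0
beta_thalassemia,Chinese_Gg+(Agdb)0,1,1,0
alpha_and_beta_thalassemia,overall,2,2,0
alpha_and_beta_thalassemia,aaa_anti3.7/aa;bN/bIVS-II-654,1,1,0
alpha_and_beta_thalassemia,HKaa/aa;bN/bCodon17,1,1,0
abnormal_hb,overall,2,2,2
abnormal_hb,Hb D-Los Angeles,2,2,2
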