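"id","name","value","unit","group","sampled","prior_lo","prior_hi","description"
1,"kappa_pi_b",0.5,"none","dynamic",1,0.01,2,"PI activation threshold by bacteria (B/B_inf)"
2,"kappa_pi_d",0.5,"none","dynamic",1,0.01,2,"PI activation threshold by damage"
3,"kappa_pi_ai",0.4,"none","dynamic",1,0.01,2,"PI inhibition threshold by AI"
4,"tau_pi",16,"hr","dynamic",1,0.5,500,"PI decay time constant"
5,"kappa_ai_pi",0.4,"none","dynamic",1,0.01,2,"AI activation threshold by PI"
6,"kappa_pi_esc",0.75,"none","dynamic",1,0.01,2,"PI level above which AI inhibition of PI is moderated (partial inhibition)"
7,"tau_ai",24,"hr","dynamic",1,0.5,500,"AI decay time constant"
8,"r_release",3.22e-06,"1/hr","dynamic",1,1e-07,1e-04,"basal neutrophil release rate from bone marrow reserve"
9,"kappa_rel_b",0.02,"none","dynamic",1,1e-04,1,"neutrophil release activation threshold by bacteria (B/B_inf)"
10,"r_release_max",3.15e-07,"1/hr","dynamic",1,1e-08,1e-05,"maximum additional release rate from bone marrow in infection"
11,"tau_nr",8,"hr","dynamic",1,0.5,500,"resting blood neutrophil death time constant"
12,"kappa_prime_b",1e+06,"CFU/ml","dynamic",1,10000,1e+08,"blood neutrophil priming threshold by bacteria"
13,"tau_prime",3,"hr","dynamic",1,0.5,500,"blood neutrophil priming time constant"
14,"kappa_act_r",0.7,"none","dynamic",1,0.01,2,"resting neutrophil activation threshold by PI"
15,"tau_act_r",20,"hr","dynamic",1,0.5,500,"resting neutrophil activation time constant"
16,"tau_np",12,"hr","dynamic",1,0.5,500,"primed neutrophil death time constant"
17,"kappa_act_p",0.6,"none","dynamic",1,0.01,2,"primed neutrophil activation threshold by PI"
18,"tau_act_p",15,"hr","dynamic",1,0.5,500,"primed neutrophil activation time constant"
19,"tau_mig",2,"hr","dynamic",1,0.5,500,"primed neutrophil migration-to-tissue time constant"
20,"tau_na",12,"hr","dynamic",1,0.5,500,"activated blood neutrophil death time constant"
21,"kappa_seq",0.5,"none","dynamic",1,0.01,2,"neutrophil sequestration activation threshold by PI"
22,"tau_seq",8,"hr","dynamic",1,0.5,500,"neutrophil sequestration time constant"
23,"tau_ns",20,"hr","dynamic",1,0.5,500,"sequestered neutrophil death time constant"
24,"tau_lung",6,"hr","dynamic",1,0.5,500,"sequestered-to-lung neutrophil migration time constant"
25,"kappa_mig_b",1e+06,"CFU/ml","dynamic",1,10000,1e+08,"activation threshold of neutrophil migration to tissue by bacteria"
26,"kappa_mig_inh",0.9,"none","dynamic",1,0.01,2,"PI threshold of migration impairment (systemic activation)"
27,"tau_nt",36,"hr","dynamic",1,0.5,500,"tissue neutrophil death time constant"
28,"kappa_lung",0.5,"none","dynamic",1,0.01,2,"sequestered neutrophil migration-to-lung activation threshold by PI"
29,"tau_nl",48,"hr","dynamic",1,0.5,500,"lung neutrophil death time constant"
30,"kappa_d_ns",0.015,"none","dynamic",1,0.001,1,"damage activation threshold by sequestered neutrophils (N_s/N_t_max)"
31,"kappa_d_nl",0.015,"none","dynamic",1,0.001,1,"damage activation threshold by lung neutrophils (N_l/N_t_max)"
32,"tau_d",40,"hr","dynamic",1,0.5,500,"damage resolution time constant"
33,"r_clp",9.4e+07,"CFU/ml/hr","dynamic",1,1e+07,1e+09,"bacterial source rate induced by CLP (scaled by severity g)"
34,"r_kill",6.61e-08,"ml/cell/hr","dynamic",1,1e-09,1e-06,"rate of bacterial removal by migrated tissue neutrophils"
35,"kappa_tnf",0.3,"none","mapping",0,0.01,2,"TNF-alpha activation threshold by PI"
36,"tau_tnf",4,"hr","mapping",0,0.5,200,"TNF-alpha observable time constant"
37,"kappa_il1b",0.35,"none","mapping",0,0.01,2,"IL-1beta activation threshold by PI"
38,"tau_il1b",6,"hr","mapping",0,0.5,200,"IL-1beta observable time constant"
39,"kappa_il6",0.3,"none","mapping",0,0.01,2,"IL-6 activation threshold by PI"
40,"tau_il6",8,"hr","mapping",0,0.5,200,"IL-6 observable time constant"
41,"kappa_il10",0.35,"none","mapping",0,0.01,2,"IL-10 activation threshold by AI"
42,"tau_il10",10,"hr","mapping",0,0.5,200,"IL-10 observable time constant"
43,"kappa_lsel",0.005,"none","mapping",0,1e-04,1,"L-selectin activation threshold by the neutrophil activation flux (flux/N_t_max per hr)"
44,"tau_lsel",8,"hr","mapping",0,0.5,200,"L-selectin observable time constant"
45,"kappa_hmgb1",0.35,"none","mapping",0,0.01,2,"HMGB1 activation threshold by damage"
46,"tau_hmgb1",24,"hr","mapping",0,0.5,200,"HMGB1 observable time constant"
47,"kappa_crt",0.4,"none","mapping",0,0.01,2,"creatinine activation threshold by damage"
48,"tau_crt",30,"hr","mapping",0,0.5,200,"creatinine observable time constant"
49,"kappa_alt",0.4,"none","mapping",0,0.01,2,"ALT activation threshold by damage"
50,"tau_alt",30,"hr","mapping",0,0.5,200,"ALT observable time constant"
51,"r_growth",0.1,"1/hr","constant",0,NA,NA,"rate of bacterial growth"
52,"r_mac",0.1,"1/hr","constant",0,NA,NA,"rate of bacterial removal by resident macrophages"
53,"b_inf",1e+09,"CFU/ml","constant",0,NA,NA,"maximum bacteria in tissue (carrying capacity)"
54,"b_mac",1e+05,"CFU/ml","constant",0,NA,NA,"bacterial level controlled by resident macrophages"
55,"nt_max",2e+07,"cells/ml","constant",0,NA,NA,"maximum neutrophils in tissue"
56,"v_bt",1.376,"none","constant",0,NA,NA,"volume ratio of blood and tissue"
57,"v_bl",0.716666666666667,"none","constant",0,NA,NA,"volume ratio of blood and lung"
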