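"strain","condition","mating_system","overrides","expected_mating","expected_meiosis","scored","provisional"
"pka1D_cyr1D","rich","homothallic","pka@=0","+","+",TRUE,FALSE
"tor2_51","rich","homothallic","tor2@=0","+","+",TRUE,FALSE
"tor2_51_cgs1D","rich","homothallic","tor2@=0;pka@=1.2","-","-",TRUE,FALSE
"tor2_51_pka1D","rich","homothallic","tor2@=0;pka@=0","+","+",TRUE,FALSE
"ste11_OE","rich","homothallic","ks_ste11r*=10;ks_ste11a*=10;ks_ste11_0*=10","+","+",TRUE,FALSE
"ste11_T82A","rich","homothallic","c_cdkste11=0","-","-",TRUE,FALSE
"ste11_T173A_S218A","rich","homothallic","ks_ste11a=0","-","-",TRUE,FALSE
"ste11_T305D_T317D","rich","homothallic","b_imphe=0;imp_boost_fixed=@phe_sat","+","+",TRUE,FALSE
"wild_type_LMB","rich","homothallic","k_exste11=0","+","+",TRUE,FALSE
"pat1_114_30C","rich","homothallic","pat1_t=0.5","+","+",TRUE,FALSE
"mts2D","rich","homothallic","kd_mei2a*=0.1;kd_mei2p*=0.1;kd_ste11*=0.1","+","+",TRUE,FALSE
"tor2_ts6_mei2D","rich","homothallic","tor2@=0;ks_mei2=0","-","-",TRUE,FALSE
"byr2_DN","rich","homothallic","phes_clamp=@phe_hyper;j_iphe*=0.3","-","+",TRUE,FALSE
"byr2_DN_mei3D","rich","homothallic","phes_clamp=@phe_hyper;j_iphe*=0.3;k_smei3=0","-","+",TRUE,FALSE
"nmt_tor2","rich","homothallic","tor2@=1;b_extor*=2;kp_tor*=3.5","-","-",TRUE,FALSE
"nmt_tor2_cyr1D","rich","homothallic","tor2@=1;b_extor*=2;kp_tor*=3.5;pka@=0","+","+",TRUE,FALSE
"wild_type","starved","homothallic","","+","+",TRUE,FALSE
"rst2D","starved","homothallic","ks_ste11r=0","-","-",TRUE,FALSE
"cgs1D","starved","homothallic","pka@=1.2","-","-",TRUE,FALSE
"mei2D","starved","homothallic","ks_mei2=0","-","-",TRUE,FALSE
"mei3D","starved","homothallic","k_smei3=0","+","-",TRUE,FALSE
"mat1pmD","starved","homothallic","k_spm=0","-","-",TRUE,FALSE
"spk1D","starved","homothallic","k_sphe=0","-","-",TRUE,FALSE
"ste11D","starved","homothallic","ks_ste11r=0;ks_ste11a=0;ks_ste11_0=0","-","-",TRUE,FALSE
"ste11_T173D_S218D","starved","homothallic","pat_imp_clamp=@pat_max","-","-",TRUE,FALSE
"ste11_T305A_T317A","starved","homothallic","b_imphe=0","+","+",TRUE,FALSE
"ste11_T82D","starved","homothallic","ste11_act=0","-","-",TRUE,FALSE
"lsk1D","starved","homothallic","k_rpol=0","-","-",TRUE,FALSE
"nmt1_ste11_lsk1D","starved","homothallic","k_rpol=0;ks_ste11r*=10;ks_ste11a*=10;ks_ste11_0*=10","+","+",TRUE,FALSE
"mei2_8A","starved","homothallic","b_dtor=0;kp_tor=0","+","+",TRUE,FALSE
"mei2_8A_SATA","starved","homothallic","b_dtor=0;kp_tor=0;kp_pat=0","-","+",TRUE,FALSE
"tor2_s65","starved","homothallic","tor2@=1;b_extor*=3;kp_tor*=3.5;b_dtor*=3","-","-",TRUE,FALSE
"tor2_s65_pREP41_mei2","starved","homothallic","tor2@=1;b_extor*=3;kp_tor*=3.5;b_dtor*=3;ks_mei2_const=@mei2oe","+","+",TRUE,FALSE
"pat1_114_34C","rich","heterothallic","pat1_t=0.001","-","+",TRUE,FALSE
"mei2D_pat1_114_34C","rich","heterothallic","pat1_t=0.001;ks_mei2=0","-","-",TRUE,FALSE
"nmt_tor2_pat1_114_34C","rich","heterothallic","pat1_t=0.001;tor2@=1;b_extor*=2;kp_tor*=3.5","-","-",TRUE,FALSE
"ste11D_pat1_114_34C","rich","heterothallic","pat1_t=0.001;ks_ste11r=0;ks_ste11a=0;ks_ste11_0=0","-","-",TRUE,FALSE
"lsk1D_pat1_114_34C","rich","heterothallic","pat1_t=0.001;k_rpol=0","-","-",TRUE,FALSE
"mei2_SATA","rich","heterothallic","kp_pat=0","-","+",TRUE,FALSE
"mei2_L_SATA","rich","heterothallic","kp_pat=0","-","+",TRUE,TRUE
"mei2_L_SATA_lsk1D","rich","heterothallic","kp_pat=0;k_rpol=0","-","-",TRUE,TRUE
"pat1D_mei2D_nmt1_mei2","rich","heterothallic","pat1_t=0.001;ks_mei2=0;ks_mei2_const=@mei2oe","-","+",TRUE,TRUE
"mei2D_nmt1_mei2","rich","heterothallic","ks_mei2=0;ks_mei2_const=@mei2oe","-","-",TRUE,FALSE
"cyr1D_M_factor","other","heterothallic","pka@=0;phes@=1",NA,NA,FALSE,FALSE
"pat1_114_34C_h90","rich","homothallic","pat1_t=0.001;k_smei3=0",NA,NA,FALSE,FALSE
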