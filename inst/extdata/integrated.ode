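# parameter file (XPPAUT 'par' dialect); time unit: minutes,
# concentrations dimensionless; model = integrated
par k_imste11=0.65000000000000002
par k_exste11=0.95708800000000005
par b_imphe=6
par b_impat=12
par h_impat=2
par b_imnut=2
par b_extor=0.9375
par imp_boost_fixed=0
par pat_imp_clamp=0
par ks_ste11r=1.2
par ks_ste11a=0.80000000000000004
par ks_ste11_0=0.0050000000000000001
par k_mste11=0.051378699999999999
par hs=4
par ste11_act=1
par kd_ste11=0.10000000000000001
par j_rst2=0.90000000000000002
par h_rst2=10
par a_rpol=0.053586500000000002
par k_rpol=0.75
par j_rpol=0.16
par h_rpol=2
par ks_mei2=0.058899100000000003
par a_mei2=0.073112499999999997
par j_smei2=0.12
par h_smei2=1
par ks_mei2_const=0
par kp_pat=0.55219700000000005
par kp_tor=0.02
par j_pmei2=0.01
par kdp_mei2=0.042323300000000001
par j_dpmei2=0.01
par kd_mei2a=0.014999999999999999
par kd_mei2p=0.050000000000000003
par w_dmei2=0.20000000000000001
par b_dpat=3.1010499999999999
par b_dtor=0.5
par k_sphe=0.25
par j_phe=0.0625
par h_phe=8
par j_phemei2=0.050000000000000003
par kd_phe=0.096477199999999999
par phes_clamp=0
par k_spm=0.0043313800000000001
par j_pm=1.1000000000000001
par h_pm=8
par kd_pm=0.012800000000000001
par k_smei3=0.017999999999999999
par kd_mei3=0.0245171
par k_as=5
par k_dis=0.00050000000000000001
par kd_cpx=0.00050000000000000001
par pat1_t=1
par j_iphe=0.78595300000000001
par c_cdkste11=1
par j_cdkste11=0.29999999999999999
par cdk_inh_clamp=0
par k1=0.029999999999999999
par k2p=0.029999999999999999
par k2pp=1
par k2ppp=0.10000000000000001
par k3p=1
par k3pp=10
par j3=0.01
par k4p=2
par k4=35
par j4=0.01
par k5p=0.0050000000000000001
par k5pp=0.29999999999999999
par j5=0.29999999999999999
par k6=0.10000000000000001
par k7=1
par k8=0.25
par j7=0.001
par j8=0.001
par k9=0.10000000000000001
par k10=0.040000000000000001
par j9=0.01
par j10=0.01
par k11=0.10000000000000001
par k12=0.01
par k12p=1
par k12pp=3
par kdiss=0.001
par k13=0.10000000000000001
par k14=0.10000000000000001
par k15=1.3999999999999999
par k16p=1
par k16pp=2
par j15=0.01
par j16=0.01
par vawee=0.25
par viwee=1
par jawee=0.01
par jiwee=0.01
par va25=1
par vi25=0.25
par ja25=0.01
par ji25=0.01
par kweep=0.14999999999999999
par kwepp=1.3
par k25p=0.050000000000000003
par k25pp=5
par mu=0.0041999999999999997
par kfill_n=0.5
par kdn=0.0040000000000000001
par ki_igo=0.20000000000000001
par kd_igo=0.050000000000000003
par j_igo=0.050000000000000003
par c_pherum1=0.25
par c_b55g1=2
par div_hi=0.40000000000000002
par div_lo=0.14999999999999999
done
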