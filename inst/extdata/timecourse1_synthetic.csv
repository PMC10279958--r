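"name","value"
"H_en",34.1719242478944
"H_EN",7.88655825242488
"H_wg",9.92301467770255
"H_IWG",42.2342311986114
"H_EWG",89.3317476487677
"H_ptc",7.58553259252598
"H_PTC",43.2742019920212
"H_ci",95.6940478887356
"H_CI",21.3071020247844
"H_CN",71.252848326377
"H_hh",88.9183691385604
"H_HH",45.8608300062549
"H_PH",32.5789866876247
"kappa_WGen",0.286245670847434
"nu_WGen",2.04123199330684
"kappa_CNen",0.00281932906118055
"nu_CNen",4.49770142109856
"kappa_CIwg",0.411568435344462
"nu_CIwg",6.92066038637276
"kappa_CNwg",0.00162972244927359
"nu_CNwg",9.65883795114914
"kappa_WGwg",0.0327453330514057
"nu_WGwg",4.71018455824139
"kappa_CIptc",0.0204496247821032
"nu_CIptc",7.09905630370156
"kappa_CNptc",0.0361875332215004
"nu_CNptc",1.47988401032657
"kappa_ENci",0.0117171176872589
"nu_ENci",2.9852423677886
"kappa_PTCCI",0.320564764469597
"nu_PTCCI",5.39628592098157
"kappa_ENhh",0.70269769267743
"nu_ENhh",6.83524796443374
"kappa_CNhh",0.0388490828944946
"nu_CNhh",1.03472972577777
"alpha_CIwg",0.0134820147957949
"beta_WGwg",27.3021321665488
"C_CI",0.130465855641178
"k_bind",0.00444053634029418
"r_exo_WG",0.011434926354874
"r_endo_WG",31.3502249887101
"T_EN",86.266612491288
"T_IWG",0.11707159616698
"T_PTC",0.0845885511261244
"T_CI",0.00719517085758934
"T_HH",168.164850029202
"PTC_0",1.44531771129036
"HH_0",2.52094993523556
"B",1
"V_max",1
"r_mem_WG",1
"r_mem_PTC",1
"r_mem_HH",1
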