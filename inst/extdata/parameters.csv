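"name","label","baseline","min","max","distribution"
"os_theta","Log-logistic OS theta, ipilimumab",0.03916796,NA,NA,"fixed"
"os_kappa","Log-logistic OS kappa, ipilimumab",1.52458,NA,NA,"fixed"
"pfs_theta","Log-logistic PFS theta, ipilimumab",0.1380415,NA,NA,"fixed"
"pfs_kappa","Log-logistic PFS kappa, ipilimumab",1.922389,NA,NA,"fixed"
"hr_os","HR of combination vs ipilimumab, OS",0.5,0.38,0.66,"lognormal"
"hr_pfs","HR of combination vs ipilimumab, PFS",0.69,0.55,0.87,"lognormal"
"resp_combo","Response percentage, combination arm",0.31,0.25,0.37,"beta"
"resp_ipi","Response percentage, ipilimumab arm",0.13,0.1,0.16,"beta"
"u_response","Utility, complete/partial response",0.88,0.7,1,"beta"
"u_stable","Utility, stable disease",0.8,0.64,0.96,"beta"
"u_progressed","Utility, progressed disease",0.52,0.42,0.62,"beta"
"price_ipilimumab_mg","Ipilimumab per mg",166,133,199,"gamma"
"price_nivolumab_mg","Nivolumab per mg",30,24,36,"gamma"
"price_pembrolizumab_mg","Pembrolizumab per mg",55,44,66,"gamma"
"cost_bsc","Best supportive care",4492,3594,5390,"gamma"
"cost_mgmt_on_tx_week","Disease management in PFD on treatment, per week",189,151,227,"gamma"
"cost_mgmt_off_tx_week","Disease management in PFD off treatment, per week",590,472,708,"gamma"
"cost_terminal","Terminal care",18042,14434,21650,"gamma"
"cost_admin_first_hr","Administration, first hour",148,119,178,"gamma"
"cost_admin_addl_hr","Administration, additional hour",31,25,38,"gamma"
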