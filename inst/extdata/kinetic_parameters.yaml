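# Reference kinetic constants for the T. versicolor / P. putida consortium
# degrading Acid Red 27. Flat key-value map; units in the package docs.
mu_max_T: 0.87
Ks_glc_T: 4.21
Kd_T: 0.09
Y_T_glc: 0.88
V_max: 0.03
K_ME_col: 1.003
K_enz: 1932
Y_enz_glc: 48.63
K_d: 0.67
K_dec: 0.13
Y_col_enz: 0.87
mu_max_P: 0.36
Ks_glc_P: 3.68
Y_P_glc: 0.55
mu_max_aP: 0.31
Ks_aro: 0.03
K_i: 0.26
Kd_P: 0.06
Y_P_aro: 0.59
a_stoich: 2.35
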