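version: '1.0'
ka_TAM: 5.0
ka_END: 7.65333
F_TAM: 1.0
F_END: 0.939155
V_TAM: 1000.0
V_NDM: 1400.0
V_4OH: 800.0
V_END: 188.027
CLf_TAM_NDM: 4.74502
CLf_TAM_4OH: 12.5262
CLf_NDM_END: 75.1801
CLf_4OH_END: 814.916
CLe_TAM: 70.0647
CLe_NDM: 20.0104
CLe_4OH: 159.312
CLe_END: 146.439
theta_EM: 1.0
theta_IM: 0.655579
theta_PM: 0.118302
cv_clearance: 0.8
cv_volume: 0.2
eps_achieve: 0.01
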