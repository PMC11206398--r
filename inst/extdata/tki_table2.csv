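substituent,lambda_cal_nm,f_cal,lambda_crystal_nm,f_crystal,ic50_nM
H,331.21,0.6391,333.17,0.6249,29
F,329.85,0.6462,330.98,0.6369,3.8
Cl,329.88,0.6611,327.54,0.5294,0.31
Br,329.99,0.6710,326.71,0.5295,0.025
I,330.51,0.6853,331.84,0.6728,0.89
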