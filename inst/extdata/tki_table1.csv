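substituent,energy_base_Eh,energy_offset_Eh,dipole_global_D,population_global_pct,crystal_strain_kcal,dipole_crystal_D,population_crystal_pct,rmsd_A
H,-933,-0.798880,5.8286,89.665,1.346,5.8063,8.880,0.135
F,-1033,-0.081728,7.7915,61.211,0.876,5.9049,13.603,0.121
Cl,-1393,-0.425183,8.0755,63.493,8.193,0.7406,0.001,0.657
Br,-3507,-0.379134,8.2320,62.711,8.279,2.4071,0.001,0.692
I,-1230,-0.996026,7.9890,54.619,1.040,5.8799,9.156,0.124
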