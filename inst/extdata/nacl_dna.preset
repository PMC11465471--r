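# NaCl around B-DNA: optimized pair-class coefficients (AMBER-style keys)
# K_GB aliases (gamma = 4 * K_GB), K_eps aliases (eps_in = K_eps)
gi_coef_1_p: 1
gi_coef_1_n: 0.05
gi_coef_1_pp: 1
gi_coef_1_pn: 0.05
gi_coef_1_nn: 1
intdiel_ion_1_p: 54
intdiel_ion_1_n: 8
intdiel_ion_1_pp: 54
intdiel_ion_1_pn: 8
intdiel_ion_1_nn: 8
cation: NA
anion: CL
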