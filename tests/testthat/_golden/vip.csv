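index_id,vip
cardiolipin_fraction,1.15454
ce_fraction,1.15454
chol_plmem,4.87221e-16
chol_sm,4.87221e-16
double_bond_index,1.15454
mono_poly,1.15454
oxpl_pl,0.0531013
pe_pc,0.518205
membrane_fluidity,0.516431
saturation_index,1.15454
sm_pc,0.518205
structural_energetic,1.15454
lyso_pl,1.15454
aa_dha,0.0531013
bmp_fraction,1.15454
cer_sm,1.15454
ceramide_fraction,1.15454
dg_pl,0.516838
ether_fraction,1.15454
ferroptosis,1.15454
lpc_pc,1.15454
lpe_pe,1.15454
lyso_o_matched,1.15454
lyso_p_matched,1.15454
lyso_matched,1.15454
pa_pl,4.87221e-16
pi_pl,0.516431
omega6_omega3,1.15454
acylcarnitine_fraction,1.15454
dg_tg,1.15454
energy_load,1.15454
neutral_polar,1.15454
storage_index,1.15454
tg_ce,1.15454
tg_fa,1.15454
tg_pl,1.15454
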