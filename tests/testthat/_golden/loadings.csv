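index_id,PC1,PC2,PC3,PC4,PC5,PC6
cardiolipin_fraction,-0.192215,-0.00576784,-0.0149605,0.00926606,0.00710766,0.0327814
ce_fraction,-0.192215,-0.00576784,-0.0149605,0.00926606,0.00710766,0.0647979
chol_plmem,0.00387244,-0.484149,-0.0221132,0.0395911,0.122556,0.00524383
chol_sm,0.00387244,-0.484149,-0.0221132,0.0395911,0.122556,0.00524383
double_bond_index,0.192215,0.00576784,0.0149605,-0.00926606,-0.00710766,-0.0560515
mono_poly,0.192215,0.00576784,0.0149605,-0.00926606,-0.00710766,0.935518
oxpl_pl,-0.00720871,-0.0133128,0.556435,-0.234852,0.304763,-0.00996327
pe_pc,-0.0912979,-0.0234338,0.428107,0.244976,-0.377546,0.0157533
membrane_fluidity,0.0840777,0.319251,0.0673492,0.576351,0.0726175,-0.0190698
saturation_index,-0.192215,-0.00576784,-0.0149605,0.00926606,0.00710766,-0.159697
sm_pc,-0.0912979,-0.0234338,0.428107,0.244976,-0.377546,0.0157533
structural_energetic,-0.192215,-0.00576784,-0.0149605,0.00926606,0.00710766,0.060015
lyso_pl,-0.192215,-0.00576784,-0.0149605,0.00926606,0.00710766,0.0678573
aa_dha,0.00720871,0.0133128,-0.556435,0.234852,-0.304763,0.00996327
bmp_fraction,-0.192215,-0.00576784,-0.0149605,0.00926606,0.00710766,0.0521728
cer_sm,0.192215,0.00576784,0.0149605,-0.00926606,-0.00710766,0.0028521
ceramide_fraction,0.192215,0.00576784,0.0149605,-0.00926606,-0.00710766,-0.00193075
dg_pl,0.0870673,-0.326527,0.0289086,-0.195273,-0.652449,-0.0315066
ether_fraction,-0.192215,-0.00576784,-0.0149605,0.00926606,0.00710766,0.060015
ferroptosis,-0.192215,-0.00576784,-0.0149605,0.00926606,0.00710766,-0.12208
lpc_pc,-0.192215,-0.00576784,-0.0149605,0.00926606,0.00710766,0.0443305
lpe_pe,-0.192215,-0.00576784,-0.0149605,0.00926606,0.00710766,0.0332997
lyso_o_matched,-0.192215,-0.00576784,-0.0149605,0.00926606,0.00710766,0.0270518
lyso_p_matched,-0.192215,-0.00576784,-0.0149605,0.00926606,0.00710766,0.0537671
lyso_matched,-0.192215,-0.00576784,-0.0149605,0.00926606,0.00710766,0.0772938
pa_pl,0.00387244,-0.484149,-0.0221132,0.0395911,0.122556,0.00524383
pi_pl,0.088976,-0.293155,0.039378,0.62643,0.22764,-0.0124368
omega6_omega3,0.192215,0.00576784,0.0149605,-0.00926606,-0.00710766,-0.111851
acylcarnitine_fraction,-0.192215,-0.00576784,-0.0149605,0.00926606,0.00710766,-0.015348
dg_tg,-0.192215,-0.00576784,-0.0149605,0.00926606,0.00710766,0.060015
energy_load,0.192215,0.00576784,0.0149605,-0.00926606,-0.00710766,-0.0772938
neutral_polar,0.192215,0.00576784,0.0149605,-0.00926606,-0.00710766,-0.060015
storage_index,0.192215,0.00576784,0.0149605,-0.00926606,-0.00710766,-0.0584208
tg_ce,0.192215,0.00576784,0.0149605,-0.00926606,-0.00710766,-0.009773
tg_fa,0.192215,0.00576784,0.0149605,-0.00926606,-0.00710766,-0.0883246
tg_pl,0.192215,0.00576784,0.0149605,-0.00926606,-0.00710766,-0.0961669
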