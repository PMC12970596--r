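index_id,display_name,category,log2fc,p_value,neg_log10_p,significant
cardiolipin_fraction,Cardiolipin Fraction,Structural,-0.30746,0,Inf,FALSE
ce_fraction,CE/Total Index,Structural,-0.31877,0,Inf,FALSE
chol_plmem,Chol/PLmem Index,Structural,0,1,-0,FALSE
chol_sm,Chol/SM Index,Structural,0,1,-0,FALSE
double_bond_index,Double Bond Index,Structural,0.0377762,0,Inf,FALSE
mono_poly,Mono/Poly Ratio,Structural,0.0445735,0,Inf,FALSE
oxpl_pl,OxPL/PL Index,Structural,0,1,-0,FALSE
pe_pc,PE/PC Index,Structural,0,1,-0,FALSE
membrane_fluidity,Membrane Fluidity Index,Structural,0,1,-0,FALSE
pl_sm,PL/SM Index,Structural,0,1,-0,FALSE
saturation_index,Saturation Index,Structural,-0.140788,0,Inf,FALSE
sm_pc,SM/PC Index,Structural,0,1,-0,FALSE
structural_energetic,Structural/Energetic,Structural,-0.962198,0,Inf,FALSE
lyso_pl,(LPC+LPE)/PL Index,Signaling,-1,0,Inf,TRUE
aa_dha,AA/DHA Index,Signaling,0,1,-0,FALSE
bmp_fraction,BMP Fraction,Signaling,-0.303631,0,Inf,FALSE
cer_sm,Cer/SM Index,Signaling,0.678072,0,Inf,FALSE
ceramide_fraction,Ceramide Fraction,Signaling,0.377583,0,Inf,FALSE
dg_pl,DG/PL Index,Signaling,3.20343e-16,1,-0,FALSE
ether_fraction,Ether Lipid Fraction,Signaling,-0.353376,0,Inf,FALSE
ferroptosis,Ferroptosis Susceptibility Index,Signaling,-0.329548,0,Inf,FALSE
gm3_gm2,GM3/GM2 Ratio,Signaling,0,1,-0,FALSE
lpc_pc,LPC/PC Index,Signaling,-1,0,Inf,TRUE
lpe_pe,LPE/PE Index,Signaling,-1,0,Inf,FALSE
lyso_o_matched,Lyso-O/PL-O (matched),Signaling,-1,0,Inf,TRUE
lyso_p_matched,Lyso-P/PL-P (matched),Signaling,-1,0,Inf,TRUE
lyso_matched,Lyso/PL (matched),Signaling,-1,0,Inf,TRUE
pa_pl,PA/PL Index,Signaling,0,1,-0,FALSE
pi_pl,PI/PL Index,Signaling,0,1,-0,FALSE
omega6_omega3,n-6/n-3 Index,Signaling,0.472812,0,Inf,FALSE
acylcarnitine_fraction,Acylcarnitine Fraction,Energy,-0.303808,0,Inf,FALSE
dg_tg,DG/TG Index,Energy,-1,0,Inf,FALSE
energy_load,Energy Load Index,Energy,0.838483,0,Inf,FALSE
neutral_polar,Neutral/Polar,Energy,0.877025,0,Inf,FALSE
storage_index,Storage Index,Energy,1.00592,0,Inf,TRUE
tg_ce,TG/CE Index,Energy,1,0,Inf,TRUE
tg_fa,TG/FA Index,Energy,1,0,Inf,TRUE
tg_pl,TG/PL Index,Energy,1,0,Inf,TRUE
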