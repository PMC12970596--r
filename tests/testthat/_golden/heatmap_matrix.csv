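sample_id,aa_dha,membrane_fluidity,double_bond_index,mono_poly,neutral_polar,storage_index,omega6_omega3,tg_fa,energy_load,tg_pl,tg_ce,cer_sm,ceramide_fraction,pi_pl,dg_pl,pa_pl,chol_plmem,chol_sm,saturation_index,ferroptosis,ce_fraction,acylcarnitine_fraction,lpe_pe,lyso_o_matched,lyso_p_matched,structural_energetic,bmp_fraction,ether_fraction,cardiolipin_fraction,lyso_matched,dg_tg,lyso_pl,lpc_pc,oxpl_pl,pe_pc,sm_pc
EXP_1,0,2.44949,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0,-1.22474,-1.93649,-1.93649,-1.93649,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,0,0,0
EXP_2,-1.93649,0,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0,0,0,0,0,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,1.93649,0,0
EXP_3,0,0,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0,1.22474,0,0,0,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,0,0,0
CTRL_3,-1.93649,0,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,0,0,0,0,0,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,1.93649,2.44949,2.44949
CTRL_1,0,0,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,0,-1.22474,0,0,0,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0,0,0
CTRL_2,0,0,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-0.912871,-2.44949,-1.22474,-1.93649,-1.93649,-1.93649,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0.912871,0,0,0
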