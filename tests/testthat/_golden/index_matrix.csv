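sample_id,cardiolipin_fraction,ce_fraction,chol_plmem,chol_sm,double_bond_index,mono_poly,odd_even,oxpl_pl,pc_unsat_sat,pe_pc,membrane_fluidity,pl_sm,saturation_index,sm_pc,structural_energetic,lyso_pl,aa_dha,bmp_fraction,cer_sm,ceramide_fraction,dg_pl,ether_fraction,ferroptosis,gm3_gm2,lpc_pc,lpe_pe,lyso_o_matched,lyso_p_matched,lyso_matched,pa_pl,pi_pl,omega6_omega3,acylcarnitine_fraction,dg_tg,energy_load,long_medium,neutral_polar,short_long,storage_index,tg_ce,tg_fa,tg_pl
CTRL_1,0.0153173,0.0569476,0.20316,1.5,2.38115,0.916624,NA,0.00255102,NA,0.268199,2.00769,6.55,0.730985,0.229885,1.68534,0.0279898,5.7,0.00129478,0.1,0.00650759,0.0305344,0.045045,0.0969267,2.33333,0.0306513,0.0428571,0.1,0.0181818,0.0405904,0.0101781,0.0767123,12.0333,0.00194342,0.0545455,0.436533,NA,0.581897,NA,0.310734,4.4,9.16667,0.559796
CTRL_2,0.0153173,0.0569476,0.20316,1.5,2.38115,0.916624,NA,0.00255102,NA,0.268199,2.00769,6.55,0.730985,0.229885,1.68534,0.0279898,5.7,0.00129478,0.1,0.00650759,0.0305344,0.045045,0.0969267,2.33333,0.0306513,0.0428571,0.1,0.0181818,0.0405904,0.0101781,0.0767123,12.0333,0.00194342,0.0545455,0.436533,NA,0.581897,NA,0.310734,4.4,9.16667,0.559796
CTRL_3,0.0153173,0.0569476,0.20316,1.5,2.38115,0.916624,NA,0.00255102,NA,0.268199,2.00769,6.55,0.730985,0.229885,1.68534,0.0279898,5.7,0.00129478,0.1,0.00650759,0.0305344,0.045045,0.0969267,2.33333,0.0306513,0.0428571,0.1,0.0181818,0.0405904,0.0101781,0.0767123,12.0333,0.00194342,0.0545455,0.436533,NA,0.581897,NA,0.310734,4.4,9.16667,0.559796
EXP_1,0.0123773,0.0456579,0.20316,1.5,2.44432,0.945386,NA,0.00255102,NA,0.268199,2.00769,6.55,0.66302,0.229885,0.865044,0.0139949,5.7,0.00104904,0.16,0.00845443,0.0305344,0.035259,0.0771329,2.33333,0.0153257,0.0214286,0.05,0.00909091,0.0202952,0.0101781,0.0767123,16.7,0.00157439,0.0272727,0.780594,NA,1.0687,NA,0.624025,8.8,18.3333,1.11959
EXP_2,0.0123773,0.0456579,0.20316,1.5,2.44432,0.945386,NA,0.00255102,NA,0.268199,2.00769,6.55,0.66302,0.229885,0.865044,0.0139949,5.7,0.00104904,0.16,0.00845443,0.0305344,0.035259,0.0771329,2.33333,0.0153257,0.0214286,0.05,0.00909091,0.0202952,0.0101781,0.0767123,16.7,0.00157439,0.0272727,0.780594,NA,1.0687,NA,0.624025,8.8,18.3333,1.11959
EXP_3,0.0123773,0.0456579,0.20316,1.5,2.44432,0.945386,NA,0.00255102,NA,0.268199,2.00769,6.55,0.66302,0.229885,0.865044,0.0139949,5.7,0.00104904,0.16,0.00845443,0.0305344,0.035259,0.0771329,2.33333,0.0153257,0.0214286,0.05,0.00909091,0.0202952,0.0101781,0.0767123,16.7,0.00157439,0.0272727,0.780594,NA,1.0687,NA,0.624025,8.8,18.3333,1.11959
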