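index_id,display_name,category,n_exp,n_ctrl,mean_exp,mean_ctrl,log2fc,se_log2fc,p_value,cohens_d,auc,power,comparable,significant,interpretation
cardiolipin_fraction,Cardiolipin Fraction,Structural,3,3,0.0123773,0.0153173,-0.30746,1.06129e-16,0,-Inf,1,1,TRUE,FALSE,NA
ce_fraction,CE/Total Index,Structural,3,3,0.0456579,0.0569476,-0.31877,1.35324e-16,0,-Inf,1,1,TRUE,FALSE,NA
chol_plmem,Chol/PLmem Index,Structural,3,3,0.20316,0.20316,0,1.13796e-16,1,0,0.5,0.05,TRUE,FALSE,NA
chol_sm,Chol/SM Index,Structural,3,3,1.5,1.5,0,1.233e-16,1,0,0.5,0.05,TRUE,FALSE,NA
double_bond_index,Double Bond Index,Structural,3,3,2.44432,2.38115,0.0377762,1.07007e-16,0,Inf,1,1,TRUE,FALSE,NA
mono_poly,Mono/Poly Ratio,Structural,3,3,0.945386,0.916624,0.0445735,1.21067e-16,0,Inf,1,1,TRUE,FALSE,NA
odd_even,Odd/Even Chain,Structural,0,0,NA,NA,NA,NA,NA,NA,NA,NA,FALSE,FALSE,NA
oxpl_pl,OxPL/PL Index,Structural,3,3,0.00255102,0.00255102,0,1.41602e-16,1,0,0.5,0.05,TRUE,FALSE,NA
pc_unsat_sat,PC Unsat/Sat Index,Structural,0,0,NA,NA,NA,NA,NA,NA,NA,NA,FALSE,FALSE,NA
pe_pc,PE/PC Index,Structural,3,3,0.268199,0.268199,0,1.21905e-16,1,0,0.666667,0.05,TRUE,FALSE,NA
membrane_fluidity,Membrane Fluidity Index,Structural,3,3,2.00769,2.00769,0,1.30278e-16,1,0,0.666667,0.05,TRUE,FALSE,NA
pl_sm,PL/SM Index,Structural,3,3,6.55,6.55,0,0,1,0,0.5,0.05,TRUE,FALSE,NA
saturation_index,Saturation Index,Structural,3,3,0.66302,0.730985,-0.140788,1.33149e-16,0,-Inf,1,1,TRUE,FALSE,NA
sm_pc,SM/PC Index,Structural,3,3,0.229885,0.229885,0,7.11113e-17,1,0,0.666667,0.05,TRUE,FALSE,NA
structural_energetic,Structural/Energetic,Structural,3,3,0.865044,1.68534,-0.962198,1.0833e-16,0,-Inf,1,1,TRUE,FALSE,NA
lyso_pl,(LPC+LPE)/PL Index,Signaling,3,3,0.0139949,0.0279898,-1,1.2645e-16,0,-Inf,1,1,TRUE,TRUE,Lysophospholipids are depleted indicating reduced phospholipase activity or enhanced reacylation
aa_dha,AA/DHA Index,Signaling,3,3,5.7,5.7,0,1.29789e-16,1,0,0.5,0.05,TRUE,FALSE,NA
bmp_fraction,BMP Fraction,Signaling,3,3,0.00104904,0.00129478,-0.303631,0,0,-Inf,1,1,TRUE,FALSE,NA
cer_sm,Cer/SM Index,Signaling,3,3,0.16,0.1,0.678072,8.17371e-17,0,Inf,1,1,TRUE,FALSE,NA
ceramide_fraction,Ceramide Fraction,Signaling,3,3,0.00845443,0.00650759,0.377583,0,0,Inf,1,1,TRUE,FALSE,NA
dg_pl,DG/PL Index,Signaling,3,3,0.0305344,0.0305344,3.20343e-16,1.15913e-16,1,Inf,0.722222,1,TRUE,FALSE,NA
ether_fraction,Ether Lipid Fraction,Signaling,3,3,0.035259,0.045045,-0.353376,0,0,-Inf,1,1,TRUE,FALSE,NA
ferroptosis,Ferroptosis Susceptibility Index,Signaling,3,3,0.0771329,0.0969267,-0.329548,1.7196e-16,0,-Inf,1,1,TRUE,FALSE,NA
gm3_gm2,GM3/GM2 Ratio,Signaling,3,3,2.33333,2.33333,0,0,1,0,0.5,0.05,TRUE,FALSE,NA
lpc_pc,LPC/PC Index,Signaling,3,3,0.0153257,0.0306513,-1,1.1547e-16,0,-Inf,1,1,TRUE,TRUE,Lysophosphatidylcholine is depleted relative to PC indicating enhanced reacylation
lpe_pe,LPE/PE Index,Signaling,3,3,0.0214286,0.0428571,-1,9.53599e-17,0,-Inf,1,1,TRUE,FALSE,NA
lyso_o_matched,Lyso-O/PL-O (matched),Signaling,3,3,0.05,0.1,-1,0,0,-Inf,1,1,TRUE,TRUE,Chain-matched ether lysophospholipids are depleted indicating reduced ether lipid turnover
lyso_p_matched,Lyso-P/PL-P (matched),Signaling,3,3,0.00909091,0.0181818,-1,1.58941e-16,0,-Inf,1,1,TRUE,TRUE,Chain-matched lysoplasmalogens are depleted indicating reduced plasmalogen turnover
lyso_matched,Lyso/PL (matched),Signaling,3,3,0.0202952,0.0405904,-1,1.4239e-16,0,-Inf,1,1,TRUE,TRUE,Chain-matched lysophospholipids are depleted relative to their precursors indicating net reacylation
pa_pl,PA/PL Index,Signaling,3,3,0.0101781,0.0101781,0,1.41964e-16,1,0,0.5,0.05,TRUE,FALSE,NA
pi_pl,PI/PL Index,Signaling,3,3,0.0767123,0.0767123,0,1.0655e-16,1,0,0.666667,0.05,TRUE,FALSE,NA
omega6_omega3,n-6/n-3 Index,Signaling,3,3,16.7,12.0333,0.472812,0,0,Inf,1,1,TRUE,FALSE,NA
acylcarnitine_fraction,Acylcarnitine Fraction,Energy,3,3,0.00157439,0.00194342,-0.303808,1.04398e-16,0,-Inf,1,1,TRUE,FALSE,NA
dg_tg,DG/TG Index,Energy,3,3,0.0272727,0.0545455,-1,1.29775e-16,0,-Inf,1,1,TRUE,FALSE,NA
energy_load,Energy Load Index,Energy,3,3,0.780594,0.436533,0.838483,0,0,Inf,1,1,TRUE,FALSE,NA
long_medium,Long/Medium Chain,Energy,0,0,NA,NA,NA,NA,NA,NA,NA,NA,FALSE,FALSE,NA
neutral_polar,Neutral/Polar,Energy,3,3,1.0687,0.581897,0.877025,0,0,Inf,1,1,TRUE,FALSE,NA
short_long,Short/Long Chain,Energy,0,0,NA,NA,NA,NA,NA,NA,NA,NA,FALSE,FALSE,NA
storage_index,Storage Index,Energy,3,3,0.624025,0.310734,1.00592,1.05218e-16,0,Inf,1,1,TRUE,TRUE,Triacylglycerol storage is expanded relative to the rest of the lipidome indicating net lipid storage
tg_ce,TG/CE Index,Energy,3,3,8.8,4.4,1,1.68136e-16,0,Inf,1,1,TRUE,TRUE,Triacylglycerols dominate over cholesteryl esters shifting storage towards fatty acid reserves
tg_fa,TG/FA Index,Energy,3,3,18.3333,9.16667,1,0,0,Inf,1,1,TRUE,TRUE,Triacylglycerols exceed free fatty acids indicating net esterification and storage
tg_pl,TG/PL Index,Energy,3,3,1.11959,0.559796,1,0,0,Inf,1,1,TRUE,TRUE,Triacylglycerols are enriched relative to phospholipids indicating storage-biased lipid partitioning
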