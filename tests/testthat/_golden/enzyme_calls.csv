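enzyme,direction,balance_exp,balance_ctrl,supporting_indices
SGMS1,indeterminate,0.266075,0.269663,
SGMS2,indeterminate,0.266075,0.269663,
SMPD1,forward-increased,0.16,0.1,
CerS2,forward-increased,0.4,0.25,
DGAT1,forward-increased,12.2222,6.11111,storage_index|tg_ce|tg_fa|tg_pl
DGAT2,forward-increased,12.2222,6.11111,tg_ce|tg_fa|tg_pl
PNPLA2,forward-decreased,0.0818182,0.163636,tg_fa
LIPE,indeterminate,2,2,tg_fa
LPL,forward-decreased,0.0818182,0.163636,lyso_matched|storage_index|tg_ce|tg_pl
PLA2G4A,forward-decreased,0.10728,0.122605,lyso_pl
LPCAT3,forward-increased,9.32143,8.15625,lyso_pl|lyso_o_matched
PEMT,indeterminate,3.72857,3.72857,
SCD1,indeterminate,NA,NA,
SOAT1,indeterminate,0.438596,0.438596,
CPT1A,indeterminate,0.075,0.075,
PLD1,indeterminate,0.0153257,0.0153257,lyso_pl|lpc_pc
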