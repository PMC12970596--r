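# For each index, a minimal profile containing only numerator-side species:
# the denominator is empty, so the index must evaluate to NA (never error).

numerator_only_profiles <- list(
  cardiolipin_fraction = c("CL 72:8" = 5),
  ce_fraction = c("CE 18:2" = 5),
  chol_plmem = c("Chol" = 5),
  chol_sm = c("Chol" = 5),
  double_bond_index = c("PC 34:1" = 0),  # zero total abundance
  mono_poly = c("FA 18:1" = 5),
  odd_even = c("FA 15:0" = 5),
  oxpl_pl = c("PC 16:0/20:4;O" = 5),
  pc_unsat_sat = c("PC 34:1" = 5),
  pe_pc = c("PE 36:2" = 5),
  membrane_fluidity = c("PC 34:1" = 5),
  pl_sm = c("PC 34:1" = 5),
  saturation_index = c("FA 16:0" = 5),
  sm_pc = c("SM 34:1;O2" = 5),
  structural_energetic = c("PC 34:1" = 5),
  lyso_pl = c("LPC 16:0" = 5),
  aa_dha = c("FA 20:4" = 5),
  bmp_fraction = c("BMP 18:1_18:1" = 5),
  cer_sm = c("Cer 42:1;O2" = 5),
  ceramide_fraction = c("Cer 42:1;O2" = 5),
  dg_pl = c("DG 34:1" = 5),
  ether_fraction = c("PC O-34:2" = 5),
  ferroptosis = c("PE 16:0/20:4" = 5),
  gm3_gm2 = c("GM3 36:1;O2" = 5),
  lpc_pc = c("LPC 16:0" = 5),
  lpe_pe = c("LPE 18:0" = 5),
  lyso_o_matched = c("LPC O-16:0" = 5),
  lyso_p_matched = c("LPE P-16:0" = 5),
  lyso_matched = c("LPC 16:0" = 5),
  pa_pl = c("PA 16:0/18:1" = 5),
  pi_pl = c("PI 18:0/20:4" = 5),
  omega6_omega3 = c("FA 18:2" = 5),
  acylcarnitine_fraction = c("CAR 16:0" = 5),
  dg_tg = c("DG 34:1" = 5),
  energy_load = c("TG 52:2" = 5),
  long_medium = c("FA 16:0" = 5),
  neutral_polar = c("TG 52:2" = 5),
  short_long = c("CAR 8:0" = 5),
  storage_index = c("TG 52:2" = 5),
  tg_ce = c("TG 52:2" = 5),
  tg_fa = c("TG 52:2" = 5),
  tg_pl = c("TG 52:2" = 5)
)

# a small fully mixed profile used by several property tests
mixed_profile <- function() {
  c("PC 16:0/18:1" = 60, "PC 34:1" = 30, "PC O-16:0/18:1" = 8,
    "LPC 16:0" = 4, "PE 16:0/20:4" = 20, "PE P-16:0/20:4" = 6,
    "LPE 18:0" = 1.5, "PS 18:0/18:1" = 12, "PI 18:0/20:4" = 14,
    "PG 16:0/18:1" = 5, "PA 16:0/18:1" = 2, "SM 34:1;O2" = 30,
    "Cer 18:1;O2/16:0" = 3, "TG 16:0_18:1_18:2" = 70, "DG 16:0/18:1" = 6,
    "CE 18:2" = 25, "CL 72:8" = 7, "CAR 16:0" = 0.9, "FA 18:1" = 12,
    "GM2 36:1;O2" = 0.15, "GM3 36:1;O2" = 0.35, "Chol" = 45)
}
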