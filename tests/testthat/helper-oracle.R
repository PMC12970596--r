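# Brute-force oracle: recomputes every index by direct summation from the
# written formulas (explicit class lists and loops), independently of the
# package's selector engine. Shares only the name parser with the
# implementation.

oracle_pool <- c(
  "PC 16:0/18:1", "PC 16:0/20:4", "PC 18:0/22:6", "PC 34:1", "PC 32:0",
  "PC O-16:0/18:1", "PC O-34:2", "PC P-16:0/20:4", "PC 16:0/20:4;O",
  "LPC 16:0", "LPC 18:1", "LPC O-16:0", "LPC P-18:0",
  "PE 16:0/20:4", "PE 18:0/22:6", "PE 36:2", "PE P-16:0/20:4",
  "PE P-18:0/22:6", "PE O-16:0/18:1",
  "LPE 18:0", "LPE 16:0", "LPE O-16:0", "LPE P-16:0",
  "PS 18:0/18:1", "PS 36:1", "PI 18:0/20:4", "PI O-18:0/20:4",
  "PG 16:0/18:1", "PA 16:0/18:1",
  "SM 34:1;O2", "SM 18:1;O2/16:0", "Cer 18:1;O2/16:0", "Cer 42:1;O2",
  "TG 16:0_18:1_18:2", "TG 16:0_16:0_18:1", "TG 52:2",
  "DG 16:0/18:1", "DG 34:1", "CE 18:2", "CE 16:0",
  "CL 72:8", "CL 18:2_18:2_18:2_18:2",
  "CAR 16:0", "CAR 12:0", "CAR 8:0", "BMP 18:1_18:1",
  "FA 16:0", "FA 18:1", "FA 18:2", "FA 15:0", "FA 17:0", "FA 18:3",
  "FA 20:4", "FA 22:6", "FA 22:4",
  "GM2 36:1;O2", "GM3 36:1;O2", "Chol")

random_profile <- function(n_species = 15, zero_frac = 0.1) {
  nm <- sample(oracle_pool, n_species)
  ab <- stats::runif(n_species, 0.05, 50)
  ab[stats::runif(n_species) < zero_frac] <- 0
  stats::setNames(ab, nm)
}

oracle_indices <- function(profile) {
  S <- lipidfun::parse_lipid_names(names(profile))
  x <- unname(unlist(profile))
  keep <- S$valid
  S <- S[keep, , drop = FALSE]
  x <- x[keep]
  n <- nrow(S)
  cls <- S$lipid_class; link <- S$linkage
  total <- sum(x)
  PL <- c("PC", "PE", "PG", "PI", "PS")

  memb <- function(classes, linkage = "ester") cls %in% classes & link %in% linkage
  # value of a ratio given numerator membership (NA when the numerator has
  # no member rows) and denominator membership
  val_ratio <- function(num_m, den_m) {
    if (!any(num_m)) return(NA_real_)
    den <- sum(x[den_m])
    if (den > 0) sum(x[num_m]) / den else NA_real_
  }
  val_frac <- function(num_m) {
    if (!any(num_m)) return(NA_real_)
    num <- sum(x[num_m])
    den <- total - num
    if (den > 0) num / den else NA_real_
  }

  # chain expansion (each chain of each resolved species, with multiplicity)
  ch_carb <- integer(); ch_db <- integer(); ch_ab <- numeric()
  for (i in seq_len(n)) {
    chi <- S$chains[[i]]
    if (!is.null(chi)) for (j in seq_len(nrow(chi))) {
      ch_carb <- c(ch_carb, chi$carbons[j])
      ch_db <- c(ch_db, chi$double_bonds[j])
      ch_ab <- c(ch_ab, x[i])
    }
  }
  chain_ratio <- function(num_m, den_m) {
    if (!length(ch_ab) || !any(num_m)) return(NA_real_)
    den <- sum(ch_ab[den_m])
    if (den > 0) sum(ch_ab[num_m]) / den else NA_real_
  }
  chain_key <- if (length(ch_carb)) paste0(ch_carb, ":", ch_db) else character(0)

  has_chain_in <- function(i, keys) {
    chi <- S$chains[[i]]
    !is.null(chi) && any(paste0(chi$carbons, ":", chi$double_bonds) %in% keys)
  }

  matched <- function(lyso_cls, intact_cls, lk) {
    lyso_i <- which(cls %in% lyso_cls & link == lk & S$n_chains == 1)
    intact_i <- which(cls %in% intact_cls & link == lk & S$n_chains > 1)
    if (!length(lyso_i) || !length(intact_i)) return(NA_real_)
    keys_of <- function(i) paste0(S$chains[[i]]$carbons, ":", S$chains[[i]]$double_bonds)
    intact_keys <- unique(unlist(lapply(intact_i, keys_of)))
    lyso_keys <- unique(unlist(lapply(lyso_i, keys_of)))
    num <- sum(x[lyso_i[vapply(lyso_i, function(i) any(keys_of(i) %in% intact_keys), logical(1))]])
    den <- sum(x[intact_i[vapply(intact_i, function(i) any(keys_of(i) %in% lyso_keys), logical(1))]])
    if (den > 0) num / den else NA_real_
  }

  dbi <- {
    d <- !is.na(S$sum_db)
    if (sum(x[d]) > 0) sum(x[d] * S$sum_db[d]) / sum(x[d]) else NA_real_
  }

  gm3 <- memb("GM3"); gm2 <- memb("GM2")
  gm3_gm2 <- val_ratio(gm3, gm2)
  if (!is.na(gm3_gm2) && sum(x[gm3]) == 0) gm3_gm2 <- NA_real_

  ferro_m <- (memb("PE") | memb("PE", "alkenyl")) &
    vapply(seq_len(n), has_chain_in, logical(1), keys = c("20:4", "22:4", "22:6"))

  list(
    cardiolipin_fraction = val_frac(memb("CL")),
    ce_fraction = val_frac(memb("CE")),
    chol_plmem = val_ratio(memb("Chol"), memb(c("PC", "PE", "PS", "PI", "SM"))),
    chol_sm = val_ratio(memb("Chol"), memb("SM")),
    double_bond_index = dbi,
    mono_poly = chain_ratio(ch_db == 1, ch_db >= 2),
    odd_even = chain_ratio(ch_carb %% 2 == 1, ch_carb %% 2 == 0),
    oxpl_pl = val_ratio(memb(PL) & S$oxidized, memb(PL) & !S$oxidized),
    pc_unsat_sat = val_ratio(memb("PC") & !is.na(S$sum_db) & S$sum_db >= 1,
                             memb("PC") & !is.na(S$sum_db) & S$sum_db == 0),
    pe_pc = val_ratio(memb("PE"), memb("PC")),
    membrane_fluidity = val_ratio(memb("PC"), memb(c("PE", "SM"))),
    pl_sm = val_ratio(memb(PL), memb("SM")),
    saturation_index = chain_ratio(ch_db == 0, ch_db >= 1),
    sm_pc = val_ratio(memb("SM"), memb("PC")),
    structural_energetic = val_ratio(memb(c("PC", "PE", "SM")), memb(c("TG", "DG"))),
    lyso_pl = val_ratio(memb(c("LPC", "LPE")), memb(PL)),
    aa_dha = chain_ratio(chain_key %in% "20:4", chain_key %in% "22:6"),
    bmp_fraction = val_frac(memb("BMP")),
    cer_sm = val_ratio(memb("Cer"), memb("SM")),
    ceramide_fraction = val_frac(memb("Cer")),
    dg_pl = val_ratio(memb("DG"), memb(PL)),
    ether_fraction = val_frac(memb(c("PC", "PE", "LPC", "LPE"), c("alkyl", "alkenyl"))),
    ferroptosis = val_frac(ferro_m),
    gm3_gm2 = gm3_gm2,
    lpc_pc = val_ratio(memb("LPC"), memb("PC")),
    lpe_pe = val_ratio(memb("LPE"), memb("PE")),
    lyso_o_matched = matched(c("LPC", "LPE"), c("PC", "PE"), "alkyl"),
    lyso_p_matched = matched(c("LPC", "LPE"), c("PC", "PE"), "alkenyl"),
    lyso_matched = matched(c("LPC", "LPE"), c("PC", "PE"), "ester"),
    pa_pl = val_ratio(memb("PA"), memb(PL)),
    pi_pl = val_ratio(memb("PI") | memb("PI", "alkyl"), memb(c("PC", "PE", "PG", "PS"))),
    omega6_omega3 = chain_ratio(chain_key %in% c("18:2", "20:4"),
                                chain_key %in% c("18:3", "22:6")),
    acylcarnitine_fraction = val_frac(memb("CAR")),
    dg_tg = val_ratio(memb("DG"), memb("TG")),
    energy_load = val_frac(memb(c("TG", "DG", "CE"))),
    long_medium = chain_ratio(ch_carb >= 16 & ch_carb <= 25, ch_carb >= 10 & ch_carb <= 15),
    neutral_polar = val_ratio(memb(c("TG", "CE")),
                              memb(c(PL, "SM", "LPC", "LPE")) | memb("PE", "alkyl")),
    short_long = chain_ratio(ch_carb >= 2 & ch_carb <= 9, ch_carb >= 16 & ch_carb <= 25),
    storage_index = val_frac(memb("TG")),
    tg_ce = val_ratio(memb("TG"), memb("CE")),
    tg_fa = val_ratio(memb("TG"), memb("FA")),
    tg_pl = val_ratio(memb("TG"), memb(PL))
  )
}
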