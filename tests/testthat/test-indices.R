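test_that("selector sums count species once, with chain-containment filters", {
  lib <- fla_index_library()
  prof <- c("TG 52:2" = 10, "PC 34:1" = 5)
  expect_equal(select_abundance(prof, selector = parse_selector("TG")), 10)
  expect_equal(select_abundance(prof, selector = parse_selector("CE")), 0)

  # polyunsaturated-PE numerator: only the 20:4-containing species counts
  prof <- c("PE 16:0/20:4" = 3, "PE 16:0/18:1" = 7)
  ferro <- lib$num_selector[[which(lib$index_id == "ferroptosis")]]
  expect_equal(select_abundance(prof, selector = ferro), 3)
})

test_that("chain totals expand with positional multiplicity", {
  ct <- chain_level_totals(c("PC 16:0/18:1" = 4))
  expect_equal(ct$abundance[ct$chain == "16:0"], 4)
  expect_equal(ct$abundance[ct$chain == "18:1"], 4)

  ct <- chain_level_totals(c("TG 16:0_16:0_18:1" = 2))
  expect_equal(ct$abundance[ct$chain == "16:0"], 4)  # two positions
  expect_equal(ct$abundance[ct$chain == "18:1"], 2)

  expect_equal(nrow(chain_level_totals(c("PC 34:1" = 9))), 0)
})

test_that("double bond index is the abundance-weighted mean of sum_db", {
  expect_equal(double_bond_index(c("PC 32:0" = 1, "PC 34:2" = 1)), 1.0)
  expect_equal(double_bond_index(c("PC 34:3" = 2)), 3.0)
  expect_equal(double_bond_index(c("PC 32:0" = 3, "PC 36:4" = 1)), 1.0)
  expect_true(is.na(double_bond_index(c("PC 34:1" = 0))))
  # species without a defined DB count (free cholesterol) are excluded
  expect_equal(double_bond_index(c("PC 34:2" = 5, "Chol" = 100)), 2.0)
})

test_that("matched lyso ratios pair chains between lyso and intact species", {
  expect_equal(matched_lyso_ratio(c("LPC 16:0" = 2, "PC 16:0/18:1" = 8)), 0.25)
  expect_true(is.na(matched_lyso_ratio(c("LPC 20:0" = 2, "PC 16:0/18:1" = 8))))
  expect_true(is.na(matched_lyso_ratio(c("LPC 16:0" = 2, "PC 34:1" = 8))))
})

test_that("index evaluation follows the published formulas on worked examples", {
  expect_equal(evaluate_index(c("TG 52:2" = 20, "PC 34:1" = 80),
                              definition = "storage_index"), 0.25)
  expect_true(is.na(evaluate_index(c("TG 52:2" = 20), definition = "storage_index")))
  expect_equal(evaluate_index(c("FA 18:2" = 5, "FA 20:4" = 3, "FA 18:3" = 2, "FA 22:6" = 2),
                              definition = "omega6_omega3"), 2.0)
})

test_that("the toy study reproduces hand-computed index values", {
  st <- toy_lipidomics_study()
  im <- compute_index_matrix(st$abundance)
  v <- im[im$sample_id == "CTRL_1", ]
  hand <- c(
    storage_index = 110 / 354,
    cardiolipin_fraction = 7 / 457,
    ce_fraction = 25 / 439,
    chol_plmem = 45 / 221.5,
    chol_sm = 1.5,
    double_bond_index = 997.7 / 419,
    mono_poly = 179.2 / 195.5,
    saturation_index = 273.9 / 374.7,
    pe_pc = 35 / 130.5,
    membrane_fluidity = 130.5 / 65,
    pl_sm = 196.5 / 30,
    sm_pc = 30 / 130.5,
    structural_energetic = 195.5 / 116,
    oxpl_pl = 0.5 / 196,
    lyso_pl = 5.5 / 196.5,
    aa_dha = 85.5 / 15,
    bmp_fraction = 0.6 / 463.4,
    cer_sm = 0.1,
    ceramide_fraction = 3 / 461,
    dg_pl = 6 / 196.5,
    ether_fraction = 20 / 444,
    ferroptosis = 41 / 423,
    gm3_gm2 = 7 / 3,
    lpc_pc = 4 / 130.5,
    lpe_pe = 1.5 / 35,
    lyso_o_matched = 0.1,
    lyso_p_matched = 0.2 / 11,
    lyso_matched = 5.5 / 135.5,
    pa_pl = 2 / 196.5,
    pi_pl = 14 / 182.5,
    omega6_omega3 = 180.5 / 15,
    acylcarnitine_fraction = 0.9 / 463.1,
    dg_tg = 6 / 110,
    energy_load = 141 / 323,
    neutral_polar = 135 / 232,
    tg_ce = 4.4,
    tg_fa = 110 / 12,
    tg_pl = 110 / 196.5
  )
  for (id in names(hand)) {
    expect_equal(v[[id]], unname(hand[id]), tolerance = 1e-12, info = id)
  }
  # indices whose components are absent from the toy are flagged unevaluated
  expect_setequal(attr(im, "not_evaluated"),
                  c("odd_even", "pc_unsat_sat", "long_medium", "short_long"))
})

test_that("indices are invariant to global scaling of a sample", {
  prof <- mixed_profile()
  lib <- fla_index_library()
  m <- tibble::tibble(lipid = names(prof), a = unname(prof), b = unname(prof) * 7.3)
  im <- compute_index_matrix(m)
  for (id in lib$index_id) {
    expect_equal(im[[id]][1], im[[id]][2], tolerance = 1e-12, info = id)
  }
})

test_that("increasing only the numerator strictly increases ratio indices", {
  prof <- mixed_profile()
  base <- evaluate_index(prof, definition = "cer_sm")
  prof2 <- prof; prof2[["Cer 18:1;O2/16:0"]] <- prof2[["Cer 18:1;O2/16:0"]] * 2
  expect_gt(evaluate_index(prof2, definition = "cer_sm"), base)

  base <- evaluate_index(prof, definition = "tg_pl")
  prof3 <- prof; prof3[["TG 16:0_18:1_18:2"]] <- prof3[["TG 16:0_18:1_18:2"]] + 10
  expect_gt(evaluate_index(prof3, definition = "tg_pl"), base)
})

test_that("double bond index stays within the sum_db range of the profile", {
  set.seed(7)
  for (rep in 1:25) {
    prof <- random_profile(12)
    v <- double_bond_index(prof)
    S <- parse_lipid_names(names(prof))
    dbs <- S$sum_db[S$valid & !is.na(S$sum_db)]
    if (!is.na(v)) {
      expect_gte(v, min(dbs))
      expect_lte(v, max(dbs))
    }
  }
})

test_that("unparseable rows are skipped and a mostly-bad matrix aborts", {
  m <- tibble::tibble(lipid = c("PC 34:1", "TG 52:2", "garbage"),
                      s1 = c(5, 2, 9), s2 = c(6, 1, 9))
  expect_message(im <- compute_index_matrix(m), "skipped 1")
  expect_equal(nrow(im), 2)

  bad <- tibble::tibble(lipid = c("PC 34:1", "nope", "zilch"), s1 = 1:3)
  expect_error(compute_index_matrix(bad), "more than half")
  expect_error(compute_index_matrix(tibble::tibble(lipid = character(), s1 = numeric())),
               "empty|sample")
})

test_that("a TG/PC-only matrix evaluates exactly the class indices it can", {
  m <- tibble::tibble(lipid = c("TG 52:2", "PC 34:1"), s1 = c(20, 80))
  im <- compute_index_matrix(m)
  expect_equal(im$storage_index, 0.25)
  expect_equal(im$tg_pl, 0.25)
  expect_equal(im$energy_load, 0.25)
  expect_true(is.na(im$cer_sm))
  expect_true(is.na(im$lyso_matched))
  expect_true(is.na(im$saturation_index))
})
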