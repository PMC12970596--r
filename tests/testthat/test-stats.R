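test_that("welch comparison matches the textbook formula and handles limits", {
  # identical groups: no evidence
  w <- welch_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)

  # separation limit: tiny variance, big shift
  w <- welch_compare(c(11, 12, 13) + 1e-9 * rnorm(3), c(1, 2, 3))
  expect_lt(w$p, 0.01)

  # random inputs against an independent hand-coded Welch oracle
  set.seed(11)
  for (rep in 1:50) {
    x <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    w <- welch_compare(x, y)
    nx <- length(x); ny <- length(y)
    vx <- var(x) / nx; vy <- var(y) / ny
    t_o <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df_o <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
    p_o <- 2 * pt(-abs(t_o), df_o)
    expect_equal(w$t, t_o, tolerance = 1e-9)
    expect_equal(w$df, df_o, tolerance = 1e-9)
    expect_equal(w$p, p_o, tolerance = 1e-9)
  }
  expect_error(welch_compare(1, c(1, 2)), ">= 2")
})

test_that("log2 fold change and its delta-method SE follow the stated form", {
  r <- log2fc_with_se(c(4, 4, 4), c(2, 2, 2))
  expect_equal(r$log2fc, 1)
  expect_equal(r$se, 0)
  r <- log2fc_with_se(c(3, 5), c(4, 4))
  expect_equal(r$log2fc, 0)
  # manual formula check
  x <- c(2.2, 2.8, 3.1); y <- c(1.1, 0.9, 1.4)
  r <- log2fc_with_se(x, y)
  se_o <- sqrt(var(x) / (3 * mean(x)^2) + var(y) / (3 * mean(y)^2)) / log(2)
  expect_equal(r$se, se_o)
  expect_error(log2fc_with_se(c(0, 0), c(1, 1)), "positive")
})

test_that("delta-method SE approximates the sampling SD of log2FC", {
  set.seed(21)
  x <- rlnorm(10, 1, 0.25); y <- rlnorm(10, 0.6, 0.25)
  r <- log2fc_with_se(x, y)
  boot <- replicate(2000, {
    log2(mean(sample(x, replace = TRUE)) / mean(sample(y, replace = TRUE)))
  })
  expect_lt(abs(r$se - sd(boot)) / sd(boot), 0.25)
})

test_that("group-label swap flips log2FC and leaves the p-value unchanged", {
  st <- generate_study(effects = data.frame(index_id = "cer_sm", log2fc = 0.8),
                       n_per_group = 6, seed = 5)
  im <- compute_index_matrix(st$abundance)
  a <- compare_indices(im, st$groups, "EXP", "CTRL")
  b <- compare_indices(im, st$groups, "CTRL", "EXP")
  cmpb <- b[match(a$index_id, b$index_id), ]
  ok <- a$comparable & cmpb$comparable
  expect_equal(a$p_value[ok], cmpb$p_value[ok], tolerance = 1e-12)
  expect_equal(a$log2fc[ok], -cmpb$log2fc[ok], tolerance = 1e-12)
})

test_that("comparison table flags, thresholds and interpretation phrases behave", {
  st <- generate_study(effects = data.frame(index_id = "storage_index", log2fc = 2),
                       n_per_group = 6, seed = 9)
  im <- compute_index_matrix(st$abundance)
  cmp <- compare_indices(im, st$groups, "EXP", "CTRL")
  expect_lte(nrow(cmp), 42)
  expect_s3_class(cmp, "fla_comparison")
  srow <- cmp[cmp$index_id == "storage_index", ]
  expect_true(srow$significant)
  lib <- fla_index_library()
  expect_equal(srow$interpretation,
               lib$phrase_high[lib$index_id == "storage_index"])
  expect_true(all(cmp$auc[cmp$comparable] >= 0.5))
  # significance definition
  with_sig <- cmp[cmp$comparable, ]
  expect_equal(with_sig$significant,
               with_sig$p_value < 0.05 & abs(with_sig$log2fc) >= 1)

  # an index NA in one whole group is not comparable
  im2 <- im
  im2$cer_sm[st$groups$group == "EXP"] <- NA
  cmp2 <- compare_indices(im2, st$groups, "EXP", "CTRL")
  expect_false(cmp2$comparable[cmp2$index_id == "cer_sm"])

  g <- glance(cmp)
  expect_equal(g$n_indices, nrow(cmp))
  expect_equal(g$group_exp, "EXP")
  expect_s3_class(tidy(cmp), "tbl_df")
})

test_that("three or more groups go through the Welch ANOVA path", {
  st <- generate_study(n_per_group = 4, seed = 3)
  im <- compute_index_matrix(st$abundance)
  g <- st$groups
  g$group <- rep(c("A", "B", "C"), length.out = nrow(g))
  cmp <- compare_indices(im, g)
  expect_s3_class(cmp, "fla_comparison_anova")
  expect_true(all(c("f_stat", "df1", "df2", "p_value") %in% names(cmp)))
  expect_false("log2fc" %in% names(cmp))
  ok <- cmp$comparable
  expect_true(any(ok))
  # cross-check one index against oneway.test directly
  id <- cmp$index_id[which(ok)[1]]
  ft <- oneway.test(im[[id]] ~ factor(g$group), var.equal = FALSE)
  expect_equal(cmp$p_value[cmp$index_id == id], ft$p.value, tolerance = 1e-12)
})

test_that("functional dominance normalises by evaluated indices per category", {
  mk_cmp <- function(df) {
    structure(df, class = c("fla_comparison", class(df)))
  }
  cmp <- mk_cmp(tibble::tibble(
    index_id = c("a", "b", "c"),
    category = c("Energy", "Energy", "Signaling"),
    log2fc = c(2, 0.1, 0.3),
    significant = c(TRUE, FALSE, FALSE),
    comparable = TRUE))
  d <- functional_dominance(cmp)
  expect_equal(d$dominance[d$category == "Energy"], 1.0)   # |2| / 2 evaluated
  expect_equal(d$dominance[d$category == "Signaling"], 0)
  expect_true(is.na(d$dominance[d$category == "Structural"]))

  # nothing significant anywhere: all zeros where evaluated
  cmp0 <- mk_cmp(tibble::tibble(index_id = "a", category = "Energy",
                                log2fc = 0.2, significant = FALSE, comparable = TRUE))
  d0 <- functional_dominance(cmp0)
  expect_equal(d0$dominance[d0$category == "Energy"], 0)

  # adding an all-NA (not comparable) index changes nothing
  cmp_na <- mk_cmp(dplyr::bind_rows(cmp,
    tibble::tibble(index_id = "z", category = "Energy", log2fc = NA_real_,
                   significant = FALSE, comparable = FALSE)))
  expect_equal(functional_dominance(cmp_na)$dominance,
               functional_dominance(cmp)$dominance)
})

test_that("raising the fold-change threshold never increases dominance", {
  st <- generate_study(effects = data.frame(index_id = c("storage_index", "cer_sm"),
                                            log2fc = c(1.5, 1.2)),
                       n_per_group = 8, seed = 13)
  im <- compute_index_matrix(st$abundance)
  d1 <- functional_dominance(compare_indices(im, st$groups, "EXP", "CTRL",
                                             fc_threshold = 0.5))
  d2 <- functional_dominance(compare_indices(im, st$groups, "EXP", "CTRL",
                                             fc_threshold = 1.0))
  ok <- !is.na(d1$dominance)
  expect_true(all(d2$dominance[ok] <= d1$dominance[ok] + 1e-12))
})

test_that("biomarker ranking uses polarity-corrected AUC and post-hoc power", {
  # perfectly separated and anti-separated both give auc* = 1
  im <- tibble::tibble(sample_id = paste0("s", 1:10),
                       up = c(6:10, 1:5) + 0.0,
                       down = c(1:5, 6:10) + 0.0,
                       noise = c(2, 9, 4, 7, 5, 6, 3, 8, 1, 10) + 0.0)
  g <- tibble::tibble(sample_id = im$sample_id,
                      group = rep(c("EXP", "CTRL"), each = 5))
  bio <- rank_biomarkers(im, g, "EXP", "CTRL")
  expect_equal(bio$auc[bio$index_id == "up"], 1.0)
  expect_equal(bio$auc[bio$index_id == "down"], 1.0)
  expect_lt(bio$auc[bio$index_id == "noise"], 1.0)

  # a sub-0.5 raw AUC is reported polarity-corrected (Mann-Whitney identity)
  x <- c(1, 2, 3, 4, 10); y <- c(5, 6, 7, 8, 9)
  raw <- unname(wilcox.test(x, y, exact = FALSE)$statistic) / 25
  expect_equal(raw, 0.2)
  im2 <- tibble::tibble(sample_id = paste0("s", 1:10), idx = c(x, y))
  bio2 <- rank_biomarkers(im2, g, "EXP", "CTRL")
  expect_equal(bio2$auc[1], 0.8)

  # power agrees with power.t.test at the observed d (equal n)
  set.seed(31)
  xx <- rnorm(8, 1); yy <- rnorm(8)
  im3 <- tibble::tibble(sample_id = paste0("s", 1:16), idx = c(xx, yy))
  g3 <- tibble::tibble(sample_id = im3$sample_id,
                       group = rep(c("EXP", "CTRL"), each = 8))
  bio3 <- rank_biomarkers(im3, g3, "EXP", "CTRL")
  d_obs <- abs(bio3$cohens_d[1])
  p_o <- power.t.test(n = 8, delta = d_obs, sd = 1, sig.level = 0.05)$power
  expect_equal(bio3$power[1], p_o, tolerance = 1e-6)

  # constant index ranks last with AUC 0.5 and d 0
  im4 <- tibble::tibble(sample_id = paste0("s", 1:10),
                        flat = rep(2, 10), up = c(6:10, 1:5) + 0.0)
  bio4 <- rank_biomarkers(im4, g, "EXP", "CTRL")
  expect_equal(bio4$index_id[nrow(bio4)], "flat")
  expect_equal(bio4$auc[bio4$index_id == "flat"], 0.5)
  expect_equal(bio4$cohens_d[bio4$index_id == "flat"], 0)
  expect_lte(nrow(bio4), 20)
})

test_that("index correlations are symmetric with unit diagonal", {
  set.seed(41)
  im <- tibble::tibble(sample_id = paste0("s", 1:30),
                       a = rnorm(30), c = rnorm(30))
  im$b <- -im$a
  r <- index_correlations(im)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r, t(r))
  expect_equal(r["a", "b"], -1)
  expect_lt(abs(r["a", "c"]), 0.5)
  # spearman option and zero-variance NA
  im$flat <- 1
  r2 <- index_correlations(im, method = "spearman")
  expect_true(all(is.na(r2["flat", c("a", "b", "c")])))
  expect_error(index_correlations(im[1:2, ]), ">= 3")
})
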