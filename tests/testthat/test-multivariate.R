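make_index_tbl <- function(n = 12, p = 8, shift_col = NULL, shift = 0,
                           groups = rep(c("EXP", "CTRL"), each = n / 2), seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("idx", seq_len(p))))
  if (!is.null(shift_col)) m[groups == "EXP", shift_col] <- m[groups == "EXP", shift_col] + shift
  tibble::tibble(sample_id = paste0("s", seq_len(n))) |>
    cbind(tibble::as_tibble(m)) |> tibble::as_tibble()
}

test_that("scaling centres, autoscales, imputes and drops as configured", {
  tbl <- make_index_tbl(10, 5)
  tbl$idx1[1:2] <- NA          # 20% NA: kept, median-imputed
  tbl$idx2[1:4] <- NA          # 40% NA: dropped
  tbl$flat <- 3                # zero variance: dropped
  expect_message(m <- scale_index_matrix(tbl), "dropping")
  expect_false(any(c("idx2", "flat") %in% colnames(m)))
  expect_false(anyNA(m))
  expect_equal(unname(colMeans(m)), rep(0, ncol(m)), tolerance = 1e-12)
  expect_equal(unname(apply(m, 2, sd)), rep(1, ncol(m)), tolerance = 1e-12)

  mc <- suppressMessages(scale_index_matrix(tbl, "center"))
  expect_equal(unname(apply(mc, 2, sd)),
               unname(apply(as.matrix(tbl[colnames(mc)]), 2,
                            function(z) sd(ifelse(is.na(z), median(z, na.rm = TRUE), z)))),
               tolerance = 1e-12)
  expect_error(scale_index_matrix(make_index_tbl(2, 3)[1:2, ]), ">= 3")
})

test_that("PCA loadings are orthonormal, explained sorted, input reconstructed", {
  m <- scale_index_matrix(make_index_tbl(15, 6, seed = 2))
  pc <- index_pca(m)
  I <- t(pc$loadings) %*% pc$loadings
  expect_equal(I, diag(ncol(I)), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-12)
  expect_equal(pc$scores %*% t(pc$loadings), m, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA separates two planted clusters on PC1", {
  tbl <- make_index_tbl(14, 8, shift_col = 1:4, shift = 6, seed = 3)
  groups <- rep(c("EXP", "CTRL"), each = 7)
  pc <- index_pca(scale_index_matrix(tbl))
  s1 <- pc$scores[, 1]
  # silhouette on PC1 with the known labels
  sil <- vapply(seq_along(s1), function(i) {
    own <- mean(abs(s1[i] - s1[groups == groups[i]][-match(i, which(groups == groups[i]))]))
    oth <- mean(abs(s1[i] - s1[groups != groups[i]]))
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("PCA on autoscaled data ignores per-index affine rescaling", {
  tbl <- make_index_tbl(12, 5, seed = 4)
  tbl2 <- tbl
  tbl2$idx1 <- tbl2$idx1 * 100 + 7
  tbl2$idx4 <- -2 * tbl2$idx4
  e1 <- index_pca(scale_index_matrix(tbl))$explained
  e2 <- index_pca(scale_index_matrix(tbl2))$explained
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("PLS-DA satisfies the VIP identity and finds the planted index", {
  tbl <- make_index_tbl(16, 10, shift_col = 3, shift = 4, seed = 5)
  g <- tibble::tibble(sample_id = tbl$sample_id,
                      group = rep(c("EXP", "CTRL"), each = 8))
  fit <- index_plsda(tbl, g)
  p <- length(fit$vip)
  expect_equal(sum(fit$vip^2), p, tolerance = 1e-8)
  expect_equal(names(which.max(fit$vip)), "idx3")
  expect_equal(mean(fit$vip^2), 1, tolerance = 1e-8)
  expect_error(index_plsda(tbl, setNames(rep("A", 16), tbl$sample_id)), "two groups")

  td <- tidy(fit)
  expect_equal(td$index_id[1], "idx3")
  expect_equal(glance(fit)$vip_sq_mean, 1, tolerance = 1e-8)
})

test_that("permuting group labels collapses the PLS-DA separation", {
  tbl <- make_index_tbl(16, 10, shift_col = 3, shift = 4, seed = 6)
  g <- tibble::tibble(sample_id = tbl$sample_id,
                      group = rep(c("EXP", "CTRL"), each = 8))
  sep <- function(fit) {
    s <- fit$scores[, 1]
    abs(mean(s[fit$groups == "EXP"]) - mean(s[fit$groups == "CTRL"])) / sd(s)
  }
  real <- sep(index_plsda(tbl, g))
  set.seed(99)
  perm <- replicate(10, {
    gp <- g; gp$group <- sample(gp$group)
    sep(index_plsda(tbl, gp))
  })
  expect_gt(real, max(perm))
})

test_that("the heatmap offers seven distances and clusters structure correctly", {
  expect_length(heatmap_distances(), 7)
  tbl <- make_index_tbl(10, 6, shift_col = 1:3, shift = 5, seed = 7)
  for (d in heatmap_distances()) {
    hm <- index_heatmap(tbl, distance = d)
    expect_s3_class(hm$sample_clust, "hclust")
    expect_s3_class(hm$index_clust, "hclust")
  }
  # two planted sample clusters recovered at k = 2
  hm <- index_heatmap(tbl)
  cl <- cutree(hm$sample_clust, k = 2)
  expect_equal(length(unique(cl[1:5])), 1)
  expect_equal(length(unique(cl[6:10])), 1)
  expect_false(cl[1] == cl[6])

  # a duplicated sample sits at distance zero and merges first
  tbl2 <- tbl
  tbl2[10, -1] <- tbl2[1, -1]
  hm2 <- suppressMessages(index_heatmap(tbl2))
  expect_equal(min(hm2$sample_clust$height), 0)
  expect_setequal(abs(hm2$sample_clust$merge[1, ]), c(1, 10))

  # top_n keeps the most variable indices and clamps with a warning
  hm3 <- index_heatmap(tbl, top_n = 3)
  expect_equal(ncol(hm3$matrix), 3)
  expect_warning(index_heatmap(tbl, top_n = 99), "clamped")
})

test_that("clustering merge heights are invariant to sample order", {
  tbl <- make_index_tbl(12, 6, seed = 8)
  hm1 <- index_heatmap(tbl)
  set.seed(1); idx <- sample(nrow(tbl))
  tbl2 <- tbl[idx, ]
  hm2 <- index_heatmap(tbl2)
  expect_equal(sort(hm1$sample_clust$height), sort(hm2$sample_clust$height),
               tolerance = 1e-12)
})

test_that("hotelling ellipses cover their score cloud centre", {
  set.seed(9)
  sc <- cbind(rnorm(10), rnorm(10))
  ell <- hotelling_ellipse(sc)
  expect_equal(nrow(ell), 100)
  expect_true(min(ell$x) < mean(sc[, 1]) && max(ell$x) > mean(sc[, 1]))
})
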