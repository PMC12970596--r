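# Univariate comparison of functional indices between groups.
#
# Conventions: log2FC = log2(mean_exp / mean_ctrl), defined only when both
# group means are positive; its standard error comes from first-order error
# propagation (delta method) on the two group means, which is coherent with
# the Welch test used for significance. P-values are unadjusted by default
# (<= 42 pre-defined indices tested); an optional BH adjustment column is
# available.

#' Welch's unequal-variance t comparison
#'
#' @param x,y Numeric vectors (NAs dropped); each group needs at least two
#'   values.
#' @return A list with `t`, `df` (Welch-Satterthwaite) and the two-sided
#'   `p`. Two identical constant groups give `t = 0`, `p = 1`.
#' @export
welch_compare <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("welch_compare needs >= 2 non-NA values per group", call. = FALSE)
  stderr <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  if (stderr < 10 * .Machine$double.eps * max(abs(mean(x)), abs(mean(y)))) {
    # both groups (numerically) constant: no within-group variability
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Log2 fold change of group means with delta-method standard error
#'
#' @param x Experimental-group values; `y` control-group values (NAs
#'   dropped). Both means must be positive.
#' @return A list with `log2fc = log2(mean(x)/mean(y))` and
#'   `se = (1/ln 2) * sqrt(s_x^2/(n_x m_x^2) + s_y^2/(n_y m_y^2))`.
#' @export
log2fc_with_se <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  mx <- mean(x); my <- mean(y)
  if (!(mx > 0 && my > 0))
    stop("log2 fold change needs positive group means", call. = FALSE)
  se <- sqrt(stats::var(x) / (length(x) * mx^2) +
             stats::var(y) / (length(y) * my^2)) / log(2)
  list(log2fc = log2(mx / my), se = se)
}

.cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sqrt(sp2) < 10 * .Machine$double.eps * max(abs(mean(x)), abs(mean(y)))) {
    if (mean(x) == mean(y)) return(0)
    return(sign(mean(x) - mean(y)) * Inf)
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

.rank_auc <- function(x, y) {
  # P(exp > ctrl) from the Mann-Whitney rank statistic, midranks for ties
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  (sum(r[seq_len(nx)]) - nx * (nx + 1) / 2) / (nx * ny)
}

.posthoc_power <- function(d, nx, ny, alpha) {
  # exact post-hoc power of the two-sample t at the observed |d| (noncentral t)
  if (!is.finite(d)) return(1)
  df <- nx + ny - 2
  ncp <- abs(d) * sqrt(nx * ny / (nx + ny))
  tc <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tc, df, ncp = ncp) + stats::pt(-tc, df, ncp = ncp)
}

.group_split_values <- function(index_matrix, groups) {
  g <- .normalize_groups(groups)
  df <- as.data.frame(index_matrix)
  idx_cols <- setdiff(names(df), "sample_id")
  g <- g[match(df$sample_id, g$sample_id), ]
  if (anyNA(g$group)) stop("every sample needs a group label", call. = FALSE)
  list(df = df, idx_cols = idx_cols, group = g$group)
}

.normalize_groups <- function(groups) {
  if (is.data.frame(groups)) {
    out <- tibble::tibble(sample_id = as.character(groups[[1]]),
                          group = as.character(groups[[2]]))
  } else {
    out <- tibble::tibble(sample_id = names(groups), group = as.character(groups))
  }
  out
}

#' Compare all indices between two groups (or by ANOVA for more)
#'
#' For two groups each comparable index gets the Welch test, the
#' delta-method log2 fold change, Cohen's d (pooled SD), the
#' polarity-corrected ROC AUC and post-hoc power; significant rows carry the
#' index's directional interpretation phrase. With more than two groups a
#' per-index Welch one-way ANOVA table (no log2FC) is returned.
#'
#' @param index_matrix A samples-by-indices tibble from
#'   [compute_index_matrix()].
#' @param groups A data frame `(sample_id, group)` or a named vector.
#' @param group_exp,group_ctrl Group labels to contrast (defaults: first two
#'   labels in order of appearance; `group_exp` is the numerator of the fold
#'   change).
#' @param p_threshold,fc_threshold Significance cut-offs: `p < p_threshold`
#'   and `|log2FC| >= fc_threshold`.
#' @param alpha Level used for the post-hoc power computation.
#' @param adjust When `TRUE`, adds a Benjamini-Hochberg `p_adj` column
#'   (significance still uses the raw p, matching the default reporting).
#' @param library Index library (for categories and phrases).
#' @return A tibble of class `fla_comparison`, one row per index, with a
#'   `comparable` flag (FALSE when a group has fewer than two non-NA values
#'   or a group mean is not positive).
#' @export
compare_indices <- function(index_matrix, groups, group_exp = NULL, group_ctrl = NULL,
                            p_threshold = 0.05, fc_threshold = 1, alpha = 0.05,
                            adjust = FALSE, library = fla_index_library()) {
  sp <- .group_split_values(index_matrix, groups)
  labels <- unique(sp$group)
  if (is.null(group_exp) && length(labels) > 2) {
    return(.compare_indices_anova(sp, p_threshold, library))
  }
  group_exp <- group_exp %||% labels[1]
  group_ctrl <- group_ctrl %||% setdiff(labels, group_exp)[1]
  if (is.na(group_ctrl)) stop("need two group labels to compare", call. = FALSE)
  lib <- library[match(sp$idx_cols, library$index_id), ]

  rows <- purrr::map_dfr(seq_along(sp$idx_cols), function(i) {
    v <- sp$df[[sp$idx_cols[i]]]
    x <- v[sp$group == group_exp]; y <- v[sp$group == group_ctrl]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    out <- tibble::tibble(
      index_id = sp$idx_cols[i],
      display_name = lib$display_name[i], category = lib$category[i],
      n_exp = length(x), n_ctrl = length(y),
      mean_exp = NA_real_, mean_ctrl = NA_real_,
      log2fc = NA_real_, se_log2fc = NA_real_, p_value = NA_real_,
      cohens_d = NA_real_, auc = NA_real_, power = NA_real_,
      comparable = FALSE, significant = FALSE, interpretation = NA_character_)
    if (length(x) < 2 || length(y) < 2) return(out)
    out$mean_exp <- mean(x); out$mean_ctrl <- mean(y)
    if (!(out$mean_exp > 0 && out$mean_ctrl > 0)) return(out)
    w <- welch_compare(x, y)
    fc <- log2fc_with_se(x, y)
    out$comparable <- TRUE
    out$log2fc <- fc$log2fc; out$se_log2fc <- fc$se
    out$p_value <- w$p
    out$cohens_d <- .cohens_d(x, y)
    out$auc <- max(.rank_auc(x, y), 1 - .rank_auc(x, y))
    out$power <- .posthoc_power(out$cohens_d, length(x), length(y), alpha)
    out$significant <- (w$p < p_threshold) && (abs(fc$log2fc) >= fc_threshold)
    if (out$significant)
      out$interpretation <- if (fc$log2fc > 0) lib$phrase_high[i] else lib$phrase_low[i]
    out
  })
  if (adjust) {
    rows$p_adj <- NA_real_
    rows$p_adj[rows$comparable] <- stats::p.adjust(rows$p_value[rows$comparable], "BH")
  }
  attr(rows, "group_exp") <- group_exp
  attr(rows, "group_ctrl") <- group_ctrl
  attr(rows, "p_threshold") <- p_threshold
  attr(rows, "fc_threshold") <- fc_threshold
  class(rows) <- c("fla_comparison", class(rows))
  rows
}

.compare_indices_anova <- function(sp, p_threshold, library) {
  lib <- library[match(sp$idx_cols, library$index_id), ]
  rows <- purrr::map_dfr(seq_along(sp$idx_cols), function(i) {
    v <- sp$df[[sp$idx_cols[i]]]
    ok <- !is.na(v)
    tab <- table(sp$group[ok])
    out <- tibble::tibble(index_id = sp$idx_cols[i],
                          display_name = lib$display_name[i],
                          category = lib$category[i],
                          n_total = sum(ok), n_groups = length(tab),
                          f_stat = NA_real_, df1 = NA_real_, df2 = NA_real_,
                          p_value = NA_real_, comparable = FALSE,
                          significant = FALSE)
    if (length(tab) < 2 || any(tab < 2)) return(out)
    ft <- tryCatch(stats::oneway.test(v[ok] ~ factor(sp$group[ok]), var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(ft) || is.na(ft$p.value)) return(out)
    out$f_stat <- unname(ft$statistic)
    out$df1 <- unname(ft$parameter[1]); out$df2 <- unname(ft$parameter[2])
    out$p_value <- ft$p.value
    out$comparable <- TRUE
    out$significant <- ft$p.value < p_threshold
    out
  })
  attr(rows, "p_threshold") <- p_threshold
  class(rows) <- c("fla_comparison_anova", class(rows))
  rows
}

#' Functional dominance per category
#'
#' Aggregates, for each functional category, the absolute log2 fold changes
#' of the indices that pass significance, normalised by the number of
#' indices effectively evaluated (comparable) in that category, so that
#' missing or filtered indices do not bias the score.
#'
#' @param comparison A two-group table from [compare_indices()].
#' @return A tibble with one row per category: `dominance`, `n_evaluated`,
#'   `n_significant`. `dominance` is `NA` when nothing was evaluated and 0
#'   when nothing reached significance.
#' @export
functional_dominance <- function(comparison) {
  stopifnot(inherits(comparison, "fla_comparison"))
  tibble::tibble(category = c("Structural", "Signaling", "Energy")) %>%
    dplyr::left_join(
      comparison %>%
        dplyr::group_by(.data$category) %>%
        dplyr::summarise(
          n_evaluated = sum(.data$comparable),
          n_significant = sum(.data$significant & .data$comparable),
          sum_abs = sum(abs(.data$log2fc[.data$significant & .data$comparable])),
          .groups = "drop"),
      by = "category") %>%
    dplyr::mutate(
      n_evaluated = dplyr::coalesce(.data$n_evaluated, 0L),
      n_significant = dplyr::coalesce(.data$n_significant, 0L),
      dominance = ifelse(.data$n_evaluated > 0,
                         dplyr::coalesce(.data$sum_abs, 0) / .data$n_evaluated,
                         NA_real_)) %>%
    dplyr::select("category", "dominance", "n_evaluated", "n_significant")
}

#' Rank indices by discriminative performance
#'
#' Orders comparable indices by Welch p-value, breaking ties by the
#' polarity-corrected AUC and then |Cohen's d|, and truncates to the top
#' `top_n`. Constant indices get AUC 0.5 and d 0 and sink to the bottom.
#'
#' @inheritParams compare_indices
#' @param top_n Number of rows to keep (default 20).
#' @return A tibble `index_id`, `display_name`, `category`, `p_value`,
#'   `auc`, `cohens_d`, `power`, `log2fc`, `rank`.
#' @export
rank_biomarkers <- function(index_matrix, groups, group_exp = NULL, group_ctrl = NULL,
                            alpha = 0.05, top_n = 20, library = fla_index_library()) {
  cmp <- compare_indices(index_matrix, groups, group_exp, group_ctrl,
                         alpha = alpha, library = library)
  cmp %>%
    dplyr::filter(.data$comparable) %>%
    dplyr::arrange(.data$p_value, dplyr::desc(.data$auc), dplyr::desc(abs(.data$cohens_d))) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::slice_head(n = top_n) %>%
    dplyr::select("rank", "index_id", "display_name", "category",
                  "p_value", "auc", "cohens_d", "power", "log2fc")
}

#' Pairwise correlation matrix of indices
#'
#' @param index_matrix A samples-by-indices tibble (needs >= 3 samples).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A symmetric correlation matrix with unit diagonal; indices with
#'   zero variance yield `NA` rows/columns. NAs in the data are handled
#'   pairwise-complete.
#' @export
index_correlations <- function(index_matrix, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  df <- as.data.frame(index_matrix)
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  if (nrow(m) < 3) stop("correlations need >= 3 samples", call. = FALSE)
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs", method = method))
}
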