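# Multivariate views of the index matrix: PCA, PLS-DA with VIP scores, and
# hierarchical clustering over seven distance measures.
#
# Before any of these, the matrix is completed: indices with more than
# `max_na` missing fraction (or zero variance) are dropped with a message,
# remaining NAs are imputed with the per-index median, and columns are
# centred and auto-scaled by default (center-only and Pareto scaling are
# available).

#' Complete and scale the index matrix for multivariate analysis
#'
#' @param index_matrix A samples-by-indices tibble from
#'   [compute_index_matrix()] (needs >= 3 samples).
#' @param method `"autoscale"` (mean 0, SD 1; default), `"center"`, or
#'   `"pareto"` (centred, divided by sqrt(SD)).
#' @param max_na Indices with a higher missing fraction are dropped (default
#'   0.2); remaining NAs are imputed with the index median.
#' @return A numeric samples-by-indices matrix with `sample_id` rownames;
#'   attribute `dropped` lists removed indices.
#' @export
scale_index_matrix <- function(index_matrix, method = c("autoscale", "center", "pareto"),
                               max_na = 0.2) {
  method <- match.arg(method)
  df <- as.data.frame(index_matrix)
  ids <- df$sample_id %||% rownames(df)
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  if (nrow(m) < 3) stop("multivariate analysis needs >= 3 samples", call. = FALSE)
  na_frac <- colMeans(is.na(m))
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  drop <- na_frac > max_na | is.na(sds) | sds == 0
  if (any(drop))
    message("dropping ", sum(drop), " index(es) before scaling: ",
            paste(utils::head(colnames(m)[drop], 5), collapse = ", "))
  m <- m[, !drop, drop = FALSE]
  if (ncol(m) == 0) stop("no indices left after NA/variance filtering", call. = FALSE)
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- stats::median(m[, j], na.rm = TRUE)
  }
  ctr <- colMeans(m)
  m <- sweep(m, 2, ctr)
  if (method == "autoscale") m <- sweep(m, 2, apply(m, 2, stats::sd), "/")
  if (method == "pareto") m <- sweep(m, 2, sqrt(apply(m, 2, stats::sd)), "/")
  rownames(m) <- ids
  attr(m, "dropped") <- colnames(df)[-1][drop]
  attr(m, "scaling") <- method
  m
}

#' PCA of the functional index matrix
#'
#' Singular-value decomposition PCA on the scaled matrix; scores times
#' transposed loadings reproduce the input within rank.
#'
#' @param index_matrix Samples-by-indices tibble, or an already scaled
#'   matrix from [scale_index_matrix()].
#' @param scaling Scaling method, passed on when `index_matrix` is unscaled.
#' @return An object of class `fla_pca`: `scores` (samples x components),
#'   `loadings` (indices x components, orthonormal), `explained`
#'   (non-increasing variance fractions), `sample_id`.
#' @export
index_pca <- function(index_matrix, scaling = "autoscale") {
  m <- if (is.matrix(index_matrix)) index_matrix else scale_index_matrix(index_matrix, scaling)
  pc <- stats::prcomp(m, center = FALSE, scale. = FALSE)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 sample_id = rownames(m)),
            class = "fla_pca")
}

#' PLS-DA of the functional index matrix with VIP scores
#'
#' Partial least squares discriminant analysis (PLS2 on one-hot group
#' labels) fitted with mixOmics; per-index Variable Importance in Projection
#' scores satisfy the identity `sum(VIP^2) = p` (the number of indices).
#'
#' @inheritParams index_pca
#' @param groups `(sample_id, group)` data frame or named vector; at least
#'   two groups.
#' @param n_components Number of latent components (default 2, matching 2-D
#'   score plots; capped at `n_samples - 1` and the number of indices).
#' @return An object of class `fla_plsda`: `scores`, `loadings`,
#'   `explained` (fraction of X variance per component), `vip` (named,
#'   from the final component), `groups`, `sample_id`, `n_components`.
#' @export
index_plsda <- function(index_matrix, groups, n_components = 2, scaling = "autoscale") {
  m <- if (is.matrix(index_matrix)) index_matrix else scale_index_matrix(index_matrix, scaling)
  g <- .normalize_groups(groups)
  y <- g$group[match(rownames(m), g$sample_id)]
  if (anyNA(y)) stop("every sample needs a group label", call. = FALSE)
  if (length(unique(y)) < 2) stop("PLS-DA needs at least two groups", call. = FALSE)
  n_components <- min(n_components, nrow(m) - 1, ncol(m))
  fit <- mixOmics::plsda(m, factor(y), ncomp = n_components, scale = FALSE)
  vip <- mixOmics::vip(fit)[, n_components]
  structure(list(scores = unname(fit$variates$X) |>
                   `dimnames<-`(list(rownames(m), paste0("comp", seq_len(n_components)))),
                 loadings = fit$loadings$X,
                 explained = unname(fit$prop_expl_var$X),
                 vip = vip, groups = y, sample_id = rownames(m),
                 n_components = n_components),
            class = "fla_plsda")
}

#' Hotelling 95% confidence ellipse for a score cloud
#'
#' @param scores Two-column matrix of component scores for one group.
#' @param level Confidence level (default 0.95).
#' @param n_points Number of polygon points.
#' @return A data frame of ellipse coordinates (`x`, `y`).
#' @export
hotelling_ellipse <- function(scores, level = 0.95, n_points = 100) {
  n <- nrow(scores)
  stopifnot(n >= 3, ncol(scores) == 2)
  ctr <- colMeans(scores)
  cv <- stats::cov(scores)
  rad <- sqrt(2 * (n - 1) / (n - 2) * stats::qf(level, 2, n - 2) / n)
  theta <- seq(0, 2 * pi, length.out = n_points)
  circ <- cbind(cos(theta), sin(theta))
  ev <- eigen(cv, symmetric = TRUE)
  pts <- circ %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors) * rad * sqrt(n)
  data.frame(x = pts[, 1] + ctr[1], y = pts[, 2] + ctr[2])
}

#' The seven heatmap distance options
#'
#' @return Character vector of the selectable distance measures.
#' @export
heatmap_distances <- function() {
  c("euclidean", "manhattan", "chebyshev", "canberra", "minkowski",
    "correlation", "spearman")
}

.fla_dist <- function(m, distance) {
  switch(distance,
         euclidean = stats::dist(m, "euclidean"),
         manhattan = stats::dist(m, "manhattan"),
         chebyshev = stats::dist(m, "maximum"),
         canberra = stats::dist(m, "canberra"),
         minkowski = stats::dist(m, "minkowski", p = 3),
         correlation = stats::as.dist(1 - stats::cor(t(m))),
         spearman = stats::as.dist(1 - stats::cor(t(m), method = "spearman")),
         stop("unknown distance: ", distance, call. = FALSE))
}

#' Hierarchically clustered heatmap of the index matrix
#'
#' Clusters both samples and indices, keeping the `top_n` most variable
#' indices, with one of seven distance measures (euclidean, manhattan,
#' chebyshev, canberra, minkowski p = 3, correlation `1 - r`, spearman
#' `1 - rho`) and complete, average, single or Ward linkage.
#'
#' @inheritParams index_pca
#' @param distance One of [heatmap_distances()].
#' @param linkage `"complete"` (default), `"average"`, `"single"` or
#'   `"ward"`.
#' @param top_n Number of indices to keep, ranked by variance after scaling
#'   (default `NULL`: all available; clamped with a warning when larger than
#'   available).
#' @param plot When `TRUE` and pheatmap is installed, draws the heatmap.
#' @return A list of class `fla_heatmap`: `matrix` (rows/columns in
#'   dendrogram order), `sample_clust` and `index_clust` (`hclust`
#'   objects), `distance`, `linkage`.
#' @export
index_heatmap <- function(index_matrix, distance = "euclidean", linkage = "complete",
                          top_n = NULL, scaling = "autoscale", plot = FALSE) {
  distance <- match.arg(distance, heatmap_distances())
  linkage <- match.arg(linkage, c("complete", "average", "single", "ward"))
  hmethod <- if (linkage == "ward") "ward.D2" else linkage
  m <- if (is.matrix(index_matrix)) index_matrix else scale_index_matrix(index_matrix, scaling)
  vars <- apply(m, 2, stats::var)
  top_n <- top_n %||% ncol(m)
  if (top_n > ncol(m)) {
    warning("top_n clamped to ", ncol(m), " available indices", call. = FALSE)
    top_n <- ncol(m)
  }
  keep <- order(vars, decreasing = TRUE)[seq_len(top_n)]
  m <- m[, sort(keep), drop = FALSE]
  hs <- stats::hclust(.fla_dist(m, distance), method = hmethod)
  hi <- stats::hclust(.fla_dist(t(m), distance), method = hmethod)
  ordered <- m[hs$order, hi$order, drop = FALSE]
  out <- structure(list(matrix = ordered, sample_clust = hs, index_clust = hi,
                        distance = distance, linkage = linkage),
                   class = "fla_heatmap")
  if (plot && requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(m, clustering_method = hmethod,
                       clustering_distance_rows = .fla_dist(m, distance),
                       clustering_distance_cols = .fla_dist(t(m), distance))
  }
  out
}
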