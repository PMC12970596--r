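# broom-style accessors for fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a comparison table
#'
#' @param x An `fla_comparison` object.
#' @param ... Ignored.
#' @return The comparison as a plain tibble (one row per index).
#' @export
tidy.fla_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a comparison
#'
#' @param x An `fla_comparison` object.
#' @param ... Ignored.
#' @return A tibble with evaluated/significant counts and the thresholds
#'   used.
#' @export
glance.fla_comparison <- function(x, ...) {
  tibble::tibble(
    n_indices = nrow(x),
    n_comparable = sum(x$comparable),
    n_significant = sum(x$significant & x$comparable),
    p_threshold = attr(x, "p_threshold"),
    fc_threshold = attr(x, "fc_threshold"),
    group_exp = attr(x, "group_exp"),
    group_ctrl = attr(x, "group_ctrl")
  )
}

#' Tidy a PCA of the index matrix
#'
#' @param x An `fla_pca` object.
#' @param matrix `"scores"`, `"loadings"` or `"explained"`.
#' @param ... Ignored.
#' @return A long tibble of the requested component matrix.
#' @export
tidy.fla_pca <- function(x, matrix = c("scores", "loadings", "explained"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "explained")
    return(tibble::tibble(component = seq_along(x$explained), explained = x$explained))
  m <- x[[matrix]]
  tibble::as_tibble(as.data.frame(m), rownames = if (matrix == "scores") "sample_id" else "index_id") %>%
    tidyr::pivot_longer(-1, names_to = "component", values_to = "value")
}

#' @rdname tidy.fla_pca
#' @export
glance.fla_pca <- function(x, ...) {
  tibble::tibble(n_components = length(x$explained),
                 explained_pc1 = x$explained[1],
                 explained_pc2 = x$explained[2])
}

#' Tidy a PLS-DA fit (VIP scores)
#'
#' @param x An `fla_plsda` object.
#' @param ... Ignored.
#' @return A tibble `index_id`, `vip`, sorted by decreasing VIP.
#' @export
tidy.fla_plsda <- function(x, ...) {
  tibble::tibble(index_id = names(x$vip), vip = unname(x$vip)) %>%
    dplyr::arrange(dplyr::desc(.data$vip))
}

#' @rdname tidy.fla_plsda
#' @export
glance.fla_plsda <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 n_indices = length(x$vip),
                 explained_x_comp1 = x$explained[1],
                 vip_sq_mean = mean(x$vip^2))
}
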