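# Evaluation of the 42 functional indices over an abundance matrix.
#
# Missing-value semantics: an index value is NA for a sample when its
# denominator is zero, when no measured species matches its numerator
# selector (required components absent from the dataset), or when it needs
# resolved chains and the dataset carries none. NA is a value here, never an
# error. Measured zeros stay zeros; no pseudocounts are added.

.as_abundance_matrix <- function(data) {
  if (is.matrix(data)) {
    lipids <- rownames(data)
    A <- data
  } else {
    df <- as.data.frame(data)
    if (ncol(df) < 2) stop("abundance table needs a lipid column plus sample columns", call. = FALSE)
    lipids <- as.character(df[[1]])
    A <- as.matrix(df[, -1, drop = FALSE])
  }
  if (is.null(lipids)) stop("lipid names missing (first column or rownames)", call. = FALSE)
  storage.mode(A) <- "double"
  list(lipids = lipids, A = A)
}

.class_member <- function(S, classes, filter = NULL) {
  memb <- rep(FALSE, nrow(S))
  for (i in seq_len(nrow(classes))) {
    lm <- switch(classes$linkage[i],
                 ester   = S$linkage == "ester",
                 alkyl   = S$linkage == "alkyl",
                 alkenyl = S$linkage == "alkenyl",
                 ether   = S$linkage %in% c("alkyl", "alkenyl"))
    memb <- memb | (!is.na(S$lipid_class) & S$lipid_class == classes$class[i] & lm)
  }
  if (!is.null(filter)) {
    memb <- memb & switch(filter$type,
      ox    = S$oxidized,
      nonox = !S$oxidized,
      db_eq = !is.na(S$sum_db) & S$sum_db == filter$value,
      db_ge = !is.na(S$sum_db) & S$sum_db >= filter$value,
      contains = vapply(seq_len(nrow(S)), function(j) {
        ch <- S$chains[[j]]
        !is.null(ch) && any(paste0(ch$carbons, ":", ch$double_bonds) %in% filter$keys)
      }, logical(1)))
  }
  memb
}

#' Sum the abundance of lipids matched by a selector
#'
#' For class selectors a multi-chain species contributes its full abundance
#' once when it (or, for `contains` filters, any of its resolved chains)
#' matches. Chain-level selectors are evaluated on [chain_level_totals()]
#' instead.
#'
#' @param profile_row Named numeric vector of abundances (names are lipid
#'   shorthand), or a single-sample data frame.
#' @param records Parsed species table from [parse_lipid_names()] covering
#'   the profile names (parsed on the fly when `NULL`).
#' @param selector A selector from [parse_selector()].
#' @return A single non-negative number (0 when nothing matches).
#' @export
select_abundance <- function(profile_row, records = NULL, selector) {
  x <- unlist(profile_row)
  if (is.null(records)) records <- parse_lipid_names(names(x))
  S <- records
  if (selector$kind == "total_complement") stop("complement selector has no standalone sum", call. = FALSE)
  if (selector$kind == "chains") {
    ct <- chain_level_totals(x, S)
    agg <- .chain_agg_from_table(ct)
    if (is.null(agg)) return(0)
    return(unname(.chain_select_sum(agg, selector)))
  }
  memb <- .class_member(S, selector$classes, selector$filter)
  unname(sum(x[S$valid & memb]))
}

#' Per-chain abundance totals of a profile
#'
#' Each resolved chain of each molecular-species lipid contributes that
#' species' abundance to its `carbons:double_bonds` key; a triacylglycerol
#' with three chains contributes three entries (positional multiplicity).
#' Sum-composition species contribute nothing.
#'
#' @inheritParams select_abundance
#' @return A tibble with columns `chain`, `carbons`, `double_bonds`,
#'   `abundance`; zero rows when no molecular-species record is present.
#' @export
chain_level_totals <- function(profile_row, records = NULL) {
  x <- unlist(profile_row)
  if (is.null(records)) records <- parse_lipid_names(names(x))
  agg <- .chain_table(records, matrix(x, ncol = 1))
  if (is.null(agg))
    return(tibble::tibble(chain = character(), carbons = integer(),
                          double_bonds = integer(), abundance = numeric()))
  tibble::tibble(chain = agg$keys, carbons = agg$carbons,
                 double_bonds = agg$db, abundance = as.numeric(agg$mat[, 1]))
}

.chain_table <- function(S, A) {
  idx <- which(S$valid & S$n_chains > 0)
  if (!length(idx)) return(NULL)
  reps <- S$n_chains[idx]
  rows <- rep(idx, reps)
  carb <- unlist(lapply(idx, function(i) S$chains[[i]]$carbons), use.names = FALSE)
  db <- unlist(lapply(idx, function(i) S$chains[[i]]$double_bonds), use.names = FALSE)
  key <- paste0(carb, ":", db)
  mat <- rowsum(A[rows, , drop = FALSE], group = key, reorder = TRUE)
  keys <- rownames(mat)
  meta <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  list(mat = mat, keys = keys,
       carbons = as.integer(meta[, 1]), db = as.integer(meta[, 2]))
}

.chain_agg_from_table <- function(ct) {
  if (nrow(ct) == 0) return(NULL)
  list(mat = matrix(ct$abundance, ncol = 1), keys = ct$chain,
       carbons = ct$carbons, db = ct$double_bonds)
}

.chain_select_sum <- function(agg, sel) {
  keep <- switch(sel$pred,
                 parity = agg$carbons %% 2L == sel$parity,
                 db_eq  = agg$db == sel$db,
                 db_ge  = agg$db >= sel$db,
                 length = agg$carbons >= sel$min & agg$carbons <= sel$max,
                 key    = agg$keys %in% sel$keys)
  colSums(agg$mat[keep, , drop = FALSE])
}

#' Abundance-weighted mean number of double bonds per lipid
#'
#' @inheritParams select_abundance
#' @return `sum(abundance * sum_db) / sum(abundance)` over all species with
#'   a defined double-bond count (sum compositions included); `NA` when that
#'   total abundance is zero.
#' @export
double_bond_index <- function(profile_row, records = NULL) {
  x <- unlist(profile_row)
  if (is.null(records)) records <- parse_lipid_names(names(x))
  unname(.db_weighted_matrix(records, matrix(x, ncol = 1))[1])
}

.db_weighted_matrix <- function(S, A) {
  keep <- S$valid & !is.na(S$sum_db)
  tot <- colSums(A[keep, , drop = FALSE])
  num <- colSums(A[keep, , drop = FALSE] * S$sum_db[keep])
  ifelse(tot > 0, num / tot, NA_real_)
}

#' Chain-matched lysophospholipid to intact phospholipid ratio
#'
#' The numerator sums lyso species (of the requested linkage) whose single
#' chain occurs among the resolved chains of at least one intact species of
#' the paired classes; the denominator sums intact species containing at
#' least one chain that occurs as a lyso species. `NA` when no
#' molecular-species data exist for the intact classes or the denominator is
#' zero.
#'
#' @inheritParams select_abundance
#' @param lyso_classes,intact_classes Character vectors of class codes
#'   (e.g. `c("LPC", "LPE")` and `c("PC", "PE")`).
#' @param linkage `"ester"`, `"alkyl"` or `"alkenyl"`.
#' @return A single value or `NA`.
#' @export
matched_lyso_ratio <- function(profile_row, records = NULL,
                               lyso_classes = c("LPC", "LPE"),
                               intact_classes = c("PC", "PE"),
                               linkage = "ester") {
  x <- unlist(profile_row)
  if (is.null(records)) records <- parse_lipid_names(names(x))
  num_sel <- list(classes = data.frame(class = lyso_classes, linkage = linkage))
  den_sel <- list(classes = data.frame(class = intact_classes, linkage = linkage))
  unname(.matched_ratio_matrix(records, matrix(x, ncol = 1), num_sel, den_sel)[1])
}

.matched_ratio_matrix <- function(S, A, num_sel, den_sel) {
  n <- ncol(A)
  lyso <- .class_member(S, num_sel$classes) & S$valid & S$n_chains == 1
  intact <- .class_member(S, den_sel$classes) & S$valid & S$n_chains > 1
  if (!any(intact) || !any(lyso)) return(rep(NA_real_, n))
  key_of <- function(i) paste0(S$chains[[i]]$carbons, ":", S$chains[[i]]$double_bonds)
  lyso_keys_by_sp <- lapply(which(lyso), key_of)
  intact_keys_by_sp <- lapply(which(intact), key_of)
  lyso_keys <- unique(unlist(lyso_keys_by_sp))
  intact_keys <- unique(unlist(intact_keys_by_sp))
  num_rows <- which(lyso)[vapply(lyso_keys_by_sp, function(k) any(k %in% intact_keys), logical(1))]
  den_rows <- which(intact)[vapply(intact_keys_by_sp, function(k) any(k %in% lyso_keys), logical(1))]
  num <- colSums(A[num_rows, , drop = FALSE])
  den <- colSums(A[den_rows, , drop = FALSE])
  ifelse(den > 0, num / den, NA_real_)
}

.evaluate_index_matrix <- function(def, S, A, total, chain_agg) {
  n <- ncol(A)
  mode <- def$mode
  if (mode == "db_weighted") return(.db_weighted_matrix(S, A))
  if (mode == "chain_matched")
    return(.matched_ratio_matrix(S, A, def$num_selector[[1]], def$den_selector[[1]]))
  if (mode == "chain_ratio") {
    if (is.null(chain_agg)) return(rep(NA_real_, n))
    num <- .chain_select_sum(chain_agg, def$num_selector[[1]])
    den <- .chain_select_sum(chain_agg, def$den_selector[[1]])
    if (all(num == 0) && !.chain_keys_present(chain_agg, def$num_selector[[1]]))
      return(rep(NA_real_, n))
    return(ifelse(den > 0, num / den, NA_real_))
  }
  num_memb <- .class_member(S, def$num_selector[[1]]$classes, def$num_selector[[1]]$filter) & S$valid
  if (!any(num_memb)) return(rep(NA_real_, n))  # required components absent
  num <- colSums(A[num_memb, , drop = FALSE])
  if (mode == "fraction") {
    den <- total - num
  } else {
    den_memb <- .class_member(S, def$den_selector[[1]]$classes, def$den_selector[[1]]$filter) & S$valid
    den <- colSums(A[den_memb, , drop = FALSE])
  }
  val <- ifelse(den > 0, num / den, NA_real_)
  if (def$index_id == "gm3_gm2") val[num == 0] <- NA_real_  # "when both are detected"
  val
}

.chain_keys_present <- function(chain_agg, sel) {
  any(switch(sel$pred,
             parity = chain_agg$carbons %% 2L == sel$parity,
             db_eq  = chain_agg$db == sel$db,
             db_ge  = chain_agg$db >= sel$db,
             length = chain_agg$carbons >= sel$min & chain_agg$carbons <= sel$max,
             key    = chain_agg$keys %in% sel$keys))
}

#' Evaluate one index definition on a single profile
#'
#' Dispatches on the definition's computation mode and applies the
#' missing-value rules (NA on zero denominator or absent components).
#'
#' @inheritParams select_abundance
#' @param definition A single-row slice of [fla_index_library()], or an
#'   index id string.
#' @return A single value or `NA`.
#' @examples
#' evaluate_index(c("TG 52:2" = 20, "PC 34:1" = 80), definition = "storage_index")
#' @export
evaluate_index <- function(profile_row, records = NULL, definition) {
  x <- unlist(profile_row)
  if (is.null(records)) records <- parse_lipid_names(names(x))
  if (is.character(definition)) {
    lib <- fla_index_library()
    definition <- lib[lib$index_id == definition, ]
    if (nrow(definition) != 1) stop("unknown index id", call. = FALSE)
  }
  A <- matrix(x, ncol = 1)
  S <- records
  total <- sum(x[S$valid])
  chain_agg <- .chain_table(S, A)
  unname(.evaluate_index_matrix(as.list(definition[1, ]) |> .relist_def(definition), S, A, total, chain_agg)[1])
}

.relist_def <- function(lst, row) {
  lst$num_selector <- row$num_selector
  lst$den_selector <- row$den_selector
  lst
}

#' Compute the samples-by-indices matrix
#'
#' Evaluates all indices of the library for every sample of a lipid
#' abundance table. Rows whose names do not parse are skipped with a
#' message; the run aborts when more than half fail.
#'
#' @param data A data frame whose first column holds lipid shorthand names
#'   and whose remaining columns are numeric sample abundances, or a numeric
#'   matrix with lipid rownames.
#' @param library An index library from [fla_index_library()].
#' @param records Optional pre-parsed species table (saves re-parsing in
#'   replicate analyses).
#' @return A tibble of class `fla_index_matrix`: `sample_id` plus one column
#'   per index. Attributes: `n_evaluated` (named count of non-NA samples per
#'   index), `not_evaluated` (ids of indices NA in every sample),
#'   `n_skipped` (unparseable input rows).
#' @examples
#' m <- tibble::tibble(lipid = c("TG 52:2", "PC 34:1"), s1 = c(20, 80), s2 = c(10, 90))
#' compute_index_matrix(m)$storage_index
#' @export
compute_index_matrix <- function(data, library = fla_index_library(), records = NULL) {
  inp <- .as_abundance_matrix(data)
  if (length(inp$lipids) == 0 || ncol(inp$A) == 0) stop("empty abundance matrix", call. = FALSE)
  S <- records %||% parse_lipid_names(inp$lipids)
  n_bad <- sum(!S$valid)
  if (n_bad > 0) {
    if (n_bad > length(inp$lipids) / 2)
      stop(sprintf("%d of %d lipid names failed to parse (more than half); aborting",
                   n_bad, length(inp$lipids)), call. = FALSE)
    message(sprintf("skipped %d unparseable lipid name(s): %s", n_bad,
                    paste(utils::head(S$lipid[!S$valid], 3), collapse = ", ")))
  }
  keep <- S$valid
  S <- S[keep, ]
  A <- inp$A[keep, , drop = FALSE]
  if (nrow(A) == 0) stop("no parseable lipid rows", call. = FALSE)
  total <- colSums(A)
  chain_agg <- .chain_table(S, A)
  vals <- lapply(seq_len(nrow(library)), function(i) {
    def <- as.list(library[i, ]) |> .relist_def(library[i, ])
    unname(.evaluate_index_matrix(def, S, A, total, chain_agg))
  })
  names(vals) <- library$index_id
  out <- tibble::as_tibble(c(list(sample_id = colnames(A) %||% paste0("S", seq_len(ncol(A)))), vals))
  n_eval <- vapply(vals, function(v) sum(!is.na(v)), integer(1))
  attr(out, "n_evaluated") <- n_eval
  attr(out, "not_evaluated") <- names(n_eval)[n_eval == 0]
  attr(out, "n_skipped") <- n_bad
  class(out) <- c("fla_index_matrix", class(out))
  out
}
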