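# From significant indices to enzyme-level hypotheses.
#
# Each enzyme of the packaged reaction table has curated lipid substrates
# and products. For a reaction A + B -> C + D the product/substrate balance
# (group-mean product sum over group-mean substrate sum) is compared between
# the experimental and control groups; a shift towards products in the
# experimental group is read as net forward drive (activity-oriented
# increase), the opposite as reduced net flux. No kinetics and no protein
# concentrations are estimated.

#' Packaged reaction table for enzyme direction calls
#'
#' A curated, human-only minimal set of lipid reactions covering the
#' recurrent enzymes of the index-protein lists; completeness is not
#' claimed. Selectors use the library mini-language (see
#' [parse_selector()]).
#'
#' @return A tibble with columns `enzyme`, `substrates`, `products`, `note`.
#' @export
reaction_library <- function() {
  path <- system.file("extdata", "reactions.csv", package = "lipidfun")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Proteins behind the significant indices
#'
#' Takes the union of the curated protein lists over all significant
#' indices, keeping provenance (which indices contributed each protein).
#'
#' @param comparison A table from [compare_indices()].
#' @param library The index library.
#' @return A tibble `protein`, `indices` (list column of index ids),
#'   `n_indices`; zero rows (with a message) when nothing is significant.
#' @export
significant_index_proteins <- function(comparison, library = fla_index_library()) {
  sig <- comparison$index_id[comparison$significant & comparison$comparable]
  if (!length(sig)) {
    message("no significant indices; empty protein set")
    return(tibble::tibble(protein = character(), indices = list(), n_indices = integer()))
  }
  lib <- library[library$index_id %in% sig, ]
  tidyr::unnest(dplyr::select(lib, "index_id", protein = "proteins"),
                cols = "protein") %>%
    dplyr::distinct(.data$protein, .data$index_id) %>%
    dplyr::group_by(.data$protein) %>%
    dplyr::summarise(indices = list(.data$index_id), n_indices = dplyr::n(),
                     .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$n_indices), .data$protein)
}

.reaction_side_sum <- function(S, A, side) {
  toks <- strsplit(side, "+", fixed = TRUE)[[1]]
  memb <- rep(FALSE, nrow(S))
  measurable <- FALSE
  for (tk in toks) {
    sel <- parse_selector(tk)
    mk <- .class_member(S, sel$classes, sel$filter) & S$valid
    measurable <- measurable || any(mk)
    memb <- memb | mk
  }
  list(sums = colSums(A[memb, , drop = FALSE]), measurable = measurable)
}

#' Call enzyme activity directions from reaction balances
#'
#' @param data Lipid abundance table (first column lipid names) or matrix.
#' @param groups `(sample_id, group)` data frame or named vector.
#' @param group_exp,group_ctrl The two group labels (defaults: first two in
#'   order of appearance).
#' @param reactions Reaction table from [reaction_library()].
#' @param tolerance Minimum relative difference between the two balances to
#'   call a direction (default 0.1); smaller shifts are `indeterminate`.
#' @param comparison Optional [compare_indices()] table used to attach the
#'   significant indices supporting each enzyme.
#' @param library Index library (for protein provenance).
#' @return A tibble of class `fla_enzyme_calls`: `enzyme`, `direction`
#'   (`forward-increased`, `forward-decreased`, `indeterminate`),
#'   `balance_exp`, `balance_ctrl`, `supporting_indices` (list column).
#'   Reactions with no measurable lipids on either side are skipped with a
#'   message.
#' @export
call_enzyme_directions <- function(data, groups, group_exp = NULL, group_ctrl = NULL,
                                   reactions = reaction_library(), tolerance = 0.1,
                                   comparison = NULL, library = fla_index_library()) {
  inp <- .as_abundance_matrix(data)
  S <- parse_lipid_names(inp$lipids)
  A <- inp$A[S$valid, , drop = FALSE]
  S <- S[S$valid, ]
  g <- .normalize_groups(groups)
  grp <- g$group[match(colnames(A), g$sample_id)]
  labels <- unique(grp[!is.na(grp)])
  group_exp <- group_exp %||% labels[1]
  group_ctrl <- group_ctrl %||% setdiff(labels, group_exp)[1]
  if (!any(grp == group_exp, na.rm = TRUE) || !any(grp == group_ctrl, na.rm = TRUE))
    stop("both groups need samples", call. = FALSE)

  sig_ids <- if (!is.null(comparison))
    comparison$index_id[comparison$significant & comparison$comparable] else character()

  rows <- purrr::map_dfr(seq_len(nrow(reactions)), function(i) {
    sub <- .reaction_side_sum(S, A, reactions$substrates[i])
    prod <- .reaction_side_sum(S, A, reactions$products[i])
    if (!sub$measurable && !prod$measurable) {
      message("reaction ", reactions$enzyme[i], " skipped: no measurable lipids")
      return(NULL)
    }
    bal <- function(side, gsel) mean(side$sums[grp == gsel & !is.na(grp)])
    se <- bal(sub, group_exp); sc <- bal(sub, group_ctrl)
    pe <- bal(prod, group_exp); pc <- bal(prod, group_ctrl)
    if (any(c(se, sc, pe, pc) == 0)) {
      direction <- "indeterminate"; be <- NA_real_; bc <- NA_real_
    } else {
      be <- pe / se; bc <- pc / sc
      # ratio test, symmetric in the two groups so calls flip exactly
      # under an EXP/CTRL swap
      direction <- if (be > bc * (1 + tolerance)) "forward-increased"
      else if (bc > be * (1 + tolerance)) "forward-decreased"
      else "indeterminate"
    }
    supp <- if (length(sig_ids)) {
      lib <- library[library$index_id %in% sig_ids, ]
      lib$index_id[purrr::map_lgl(lib$proteins, ~ reactions$enzyme[i] %in% .x)]
    } else character()
    tibble::tibble(enzyme = reactions$enzyme[i], direction = direction,
                   balance_exp = be, balance_ctrl = bc,
                   supporting_indices = list(supp))
  })
  attr(rows, "group_exp") <- group_exp
  attr(rows, "group_ctrl") <- group_ctrl
  attr(rows, "tolerance") <- tolerance
  class(rows) <- c("fla_enzyme_calls", class(rows))
  rows
}

.string_annotation_sources <- c("GO-BP", "GO-MF", "GO-CC", "KEGG", "Pfam",
                                "InterPro", "UniProt keywords", "Reactome")

#' Build an offline STRING network request payload
#'
#' Serialises the request a STRING query would use (endpoint path, seed
#' identifiers, parameters). No network call is performed; the payload can
#' be submitted separately or written to disk for provenance.
#'
#' @param proteins Character vector of seed gene symbols (must be
#'   non-empty).
#' @param network_type `"full"` (default) or `"physical"`.
#' @param score_threshold Minimum interaction confidence, 0-1000 scale
#'   (default 400).
#' @param add_nodes Number of neighbouring proteins to add (default 0).
#' @param annotation_source Node-colouring annotation system; one of GO-BP,
#'   GO-MF, GO-CC, KEGG, Pfam, InterPro, UniProt keywords, Reactome.
#' @param organism NCBI taxon of the study organism. Protein lists ship for
#'   human only (9606, the default); the field is reserved for other model
#'   organisms.
#' @param path Optional file to write the payload to as JSON.
#' @return A list of class `fla_string_request` with `endpoint` and
#'   `parameters`.
#' @export
build_string_request <- function(proteins, network_type = c("full", "physical"),
                                 score_threshold = 400, add_nodes = 0,
                                 annotation_source = "GO-BP",
                                 organism = 9606, path = NULL) {
  if (!length(proteins)) stop("empty protein list", call. = FALSE)
  network_type <- match.arg(network_type)
  annotation_source <- match.arg(annotation_source, .string_annotation_sources)
  stopifnot(score_threshold >= 0, score_threshold <= 1000, add_nodes >= 0)
  payload <- list(
    endpoint = "https://string-db.org/api/json/network",
    parameters = list(
      identifiers = paste(sort(unique(proteins)), collapse = "%0d"),
      species = organism,
      required_score = score_threshold,
      network_type = network_type,
      add_white_nodes = add_nodes,
      annotation_source = annotation_source,
      caller_identity = "lipidfun"
    )
  )
  class(payload) <- "fla_string_request"
  if (!is.null(path))
    jsonlite::write_json(unclass(payload), path, auto_unbox = TRUE, pretty = TRUE)
  payload
}

#' Annotation sources selectable for STRING node colouring
#'
#' @return Character vector of the eight selectable annotation systems.
#' @export
string_annotation_sources <- function() .string_annotation_sources
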