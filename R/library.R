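# The declarative index library: 42 functional indices in three categories
# (Structural 15, Signaling 17, Energy 10), shipped as a human-editable CSV.
#
# Selector mini-language used in the numerator/denominator columns:
#   "@total"                 denominator = total lipid content minus numerator
#   "PC+PE+PS"               class union; a token may carry a linkage
#                            qualifier: "PC O" (alkyl), "PC P" (alkenyl),
#                            "PC O?" (either ether form); bare codes match
#                            ester (diacyl) species only
#   "...&ox" / "...&nonox"   restrict to oxidized / non-oxidized species
#   "...&db==0" / "...&db>=1"  species-level double-bond filter (sum_db)
#   "...&contains:20:4|22:4|22:6"  species with >= 1 resolved chain in the set
#   "#db==1", "#odd", "#len:16-25", "#key:18:2|20:4"  chain-level selectors
#                            evaluated on the chain abundance table

.fla_library_cache <- new.env(parent = emptyenv())

#' Load the packaged library of 42 functional lipid indices
#'
#' Each definition carries its biochemical category, computation mode,
#' numerator/denominator selectors, the curated human protein list, the
#' directional interpretation phrases and a literature tag.
#'
#' @param path Optional path to an alternative library CSV with the same
#'   columns (the packaged file is the default).
#' @return A tibble with one row per index and list-columns `num_selector`,
#'   `den_selector`, `proteins` holding parsed selector structures and gene
#'   symbol vectors.
#' @examples
#' lib <- fla_index_library()
#' nrow(lib)            # 42
#' table(lib$category)  # Energy 10, Signaling 17, Structural 15
#' @export
fla_index_library <- function(path = NULL) {
  key <- path %||% "packaged"
  hit <- .fla_library_cache[[key]]
  if (!is.null(hit)) return(hit)
  file <- path %||% system.file("extdata", "index_library.csv", package = "lipidfun")
  if (!nzchar(file) || !file.exists(file)) stop("index library file not found", call. = FALSE)
  raw <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  needed <- c("index_id", "display_name", "category", "mode", "numerator",
              "denominator", "match_linkage", "proteins", "requires_chains",
              "reference_tag", "phrase_high", "phrase_low")
  if (!all(needed %in% names(raw)) || anyNA(raw$index_id) ||
      anyDuplicated(raw$index_id) > 0 ||
      !all(raw$category %in% c("Structural", "Signaling", "Energy")) ||
      !all(raw$mode %in% c("fraction", "ratio", "chain_ratio", "db_weighted", "chain_matched")))
    stop("index library file is corrupt", call. = FALSE)
  lib <- raw %>%
    dplyr::mutate(
      requires_chains = as.logical(.data$requires_chains),
      proteins = strsplit(.data$proteins, ";", fixed = TRUE),
      num_selector = purrr::map(.data$numerator, parse_selector),
      den_selector = purrr::map(.data$denominator, parse_selector)
    )
  assign(key, lib, envir = .fla_library_cache)
  lib
}

#' Parse one selector expression of the index library
#'
#' @param text A selector string in the library mini-language (see the
#'   column documentation of the packaged `index_library.csv`), or `NA`.
#' @return A list describing the selector: `kind` (`"classes"`, `"chains"`,
#'   `"total_complement"`, `"none"`), a `classes` data frame with `class` and
#'   `linkage` (ester/alkyl/alkenyl/ether), an optional species `filter`, and
#'   for chain selectors the chain predicate fields.
#' @export
parse_selector <- function(text) {
  if (is.na(text) || !nzchar(text)) return(list(kind = "none"))
  if (text == "@total") return(list(kind = "total_complement"))
  if (startsWith(text, "#")) return(.parse_chain_selector(substring(text, 2)))
  parts <- strsplit(text, "&", fixed = TRUE)[[1]]
  toks <- strsplit(parts[1], "+", fixed = TRUE)[[1]]
  classes <- do.call(rbind, lapply(toks, function(tk) {
    tk <- trimws(tk)
    mm <- regmatches(tk, regexec("^([A-Za-z][A-Za-z0-9]*)( (O\\?|O|P))?$", tk))[[1]]
    if (length(mm) == 0) stop("bad selector token: ", tk, call. = FALSE)
    linkage <- switch(mm[4], "O" = "alkyl", "P" = "alkenyl", "O?" = "ether", "ester")
    data.frame(class = mm[2], linkage = linkage)
  }))
  filt <- NULL
  if (length(parts) > 1) {
    f <- parts[2]
    filt <- if (f == "ox") list(type = "ox")
    else if (f == "nonox") list(type = "nonox")
    else if (grepl("^db==[0-9]+$", f)) list(type = "db_eq", value = as.integer(substring(f, 5)))
    else if (grepl("^db>=[0-9]+$", f)) list(type = "db_ge", value = as.integer(substring(f, 5)))
    else if (startsWith(f, "contains:"))
      list(type = "contains", keys = strsplit(substring(f, 10), "|", fixed = TRUE)[[1]])
    else stop("bad selector filter: ", f, call. = FALSE)
  }
  list(kind = "classes", classes = classes, filter = filt)
}

.parse_chain_selector <- function(f) {
  if (f == "odd") return(list(kind = "chains", pred = "parity", parity = 1L))
  if (f == "even") return(list(kind = "chains", pred = "parity", parity = 0L))
  m <- regmatches(f, regexec("^db([=>]=)([0-9]+)$", f))[[1]]
  if (length(m)) {
    return(list(kind = "chains", pred = if (m[2] == "==") "db_eq" else "db_ge",
                db = as.integer(m[3])))
  }
  m <- regmatches(f, regexec("^len:([0-9]+)-([0-9]+)$", f))[[1]]
  if (length(m)) {
    return(list(kind = "chains", pred = "length",
                min = as.integer(m[2]), max = as.integer(m[3])))
  }
  if (startsWith(f, "key:")) {
    return(list(kind = "chains", pred = "key",
                keys = strsplit(substring(f, 5), "|", fixed = TRUE)[[1]]))
  }
  stop("bad chain selector: #", f, call. = FALSE)
}

#' Curated protein vocabulary of the index library
#'
#' @return A character vector: the union of all gene symbols attached to the
#'   42 indices.
#' @export
index_protein_vocabulary <- function() {
  sort(unique(unlist(fla_index_library()$proteins)))
}
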