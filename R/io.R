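# Reading study inputs and orchestrating the full workflow.

#' Read a lipid abundance matrix from CSV/TSV
#'
#' Lipids are expected in rows (first column = shorthand names, remaining
#' columns = samples); with `orientation = "auto"` the table is transposed
#' when the header parses better as lipid names than the first column does.
#' Negative values are a hard failure (with coordinates); missing cells
#' become 0 with a logged count; duplicate lipid names are suffixed;
#' duplicate sample ids abort.
#'
#' @param path CSV or TSV file.
#' @param orientation `"auto"`, `"lipids_rows"` or `"lipids_cols"`.
#' @return A tibble (lipid column + numeric sample columns) with attributes
#'   `n_missing_cells` and `parse` (the species table with per-row status).
#' @export
read_lipid_matrix <- function(path, orientation = c("auto", "lipids_rows", "lipids_cols")) {
  orientation <- match.arg(orientation)
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, name_repair = "minimal")
  if (ncol(df) < 2) stop("need at least one sample column", call. = FALSE)
  if (orientation == "auto") {
    rate_rows <- mean(parse_lipid_names(as.character(df[[1]]))$valid)
    rate_cols <- mean(parse_lipid_names(names(df)[-1])$valid)
    orientation <- if (rate_cols > rate_rows) "lipids_cols" else "lipids_rows"
  }
  if (orientation == "lipids_cols") {
    lip <- names(df)[-1]
    samp <- as.character(df[[1]])
    vals <- t(as.matrix(df[, -1, drop = FALSE]))
    df <- tibble::as_tibble(cbind(tibble::tibble(lipid = lip),
                                  stats::setNames(as.data.frame(vals), samp)))
  }
  lipids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative abundance at lipid '%s', sample '%s'",
                 lipids[neg[1, 1]], colnames(m)[neg[1, 2]]), call. = FALSE)
  n_missing <- sum(is.na(m))
  if (n_missing > 0) {
    message("treated ", n_missing, " missing cell(s) as 0")
    m[is.na(m)] <- 0
  }
  if (anyDuplicated(colnames(m)) > 0) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(lipids) > 0) {
    message("suffixed ", sum(duplicated(lipids)), " duplicate lipid name(s)")
    lipids <- make.unique(lipids, sep = "#")
  }
  parse <- parse_lipid_names(sub("#[0-9]+$", "", lipids))
  if (sum(!parse$valid) > 0)
    message(sum(!parse$valid), " lipid name(s) will be skipped by index computation")
  out <- tibble::as_tibble(cbind(tibble::tibble(lipid = lipids), tibble::as_tibble(m)))
  attr(out, "n_missing_cells") <- n_missing
  attr(out, "parse") <- parse
  out
}

#' Read a sample-to-group mapping
#'
#' @param path CSV/TSV with two columns: sample id, group label.
#' @return A tibble `sample_id`, `group`.
#' @export
read_group_map <- function(path) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  tibble::tibble(sample_id = as.character(df[[1]]), group = as.character(df[[2]]))
}

.fmt6 <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) NA_character_ else sprintf("%.6g", v)
    }, character(1))
    return(out)
  }
  as.character(x)
}

#' Write a table as CSV with 6-significant-digit numbers and "NA" literals
#'
#' @param df A data frame; list columns are collapsed with `|`.
#' @param path Output file.
#' @export
write_fla_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) df[[j]] <- vapply(df[[j]], paste, character(1), collapse = "|")
    df[[j]] <- .fmt6(df[[j]])
  }
  readr::write_csv(tibble::as_tibble(df), path, na = "NA")
  invisible(path)
}

#' Run the full functional-index workflow and write a result bundle
#'
#' Computes the index matrix, two-group statistics (or per-index Welch
#' ANOVA for more than two groups), dominance, biomarker ranking,
#' correlations, PCA, PLS-DA, the clustered heatmap, enzyme direction calls
#' and the STRING request payload, writing each result as CSV/JSON into
#' `out_dir` plus a `run_log.txt` with seed, thresholds and version. All
#' CSV output is deterministic (byte-identical across runs at the same
#' inputs and seed).
#'
#' @param data An `fla_study` from [generate_study()] /
#'   [toy_lipidomics_study()], or a lipid abundance table (first column
#'   shorthand names).
#' @param groups `(sample_id, group)` table; taken from the study object
#'   when `data` is one.
#' @param out_dir Output directory (created if needed).
#' @param group_exp,group_ctrl Labels of the experimental and control
#'   groups (two-group analyses).
#' @param p_threshold,fc_threshold Significance cut-offs.
#' @param scaling,distance,linkage Multivariate options.
#' @param seed Seed recorded in the log and used for any randomised step.
#' @param write_plots When `TRUE`, also saves PNG figures for the main
#'   plots.
#' @return Invisibly, a list with the in-memory results and the output
#'   paths.
#' @export
run_fla_pipeline <- function(data, groups = NULL, out_dir,
                             group_exp = NULL, group_ctrl = NULL,
                             p_threshold = 0.05, fc_threshold = 1,
                             scaling = "autoscale", distance = "euclidean",
                             linkage = "complete", seed = 1,
                             write_plots = FALSE) {
  if (inherits(data, "fla_study")) {
    groups <- groups %||% data$groups
    data <- data$abundance
  }
  if (is.null(groups)) stop("groups are required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  g <- .normalize_groups(groups)
  n_groups <- length(unique(g$group))
  paths <- character()
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    write_fla_csv(df, p)
    paths[[name]] <<- p
    p
  }

  im <- compute_index_matrix(data)
  put(im, "index_matrix.csv")

  res <- list(index_matrix = im)

  if (n_groups == 2) {
    cmp <- compare_indices(im, g, group_exp, group_ctrl,
                           p_threshold = p_threshold, fc_threshold = fc_threshold)
    put(cmp, "functional_summary.csv")
    dom <- functional_dominance(cmp)
    put(dom, "dominance.csv")
    volcano <- cmp %>%
      dplyr::filter(.data$comparable) %>%
      dplyr::mutate(neg_log10_p = -log10(.data$p_value)) %>%
      dplyr::select("index_id", "display_name", "category", "log2fc",
                    "p_value", "neg_log10_p", "significant")
    put(volcano, "volcano_table.csv")
    bio <- rank_biomarkers(im, g, attr(cmp, "group_exp"), attr(cmp, "group_ctrl"))
    put(bio, "biomarker_top20.csv")
    res <- c(res, list(comparison = cmp, dominance = dom, biomarkers = bio))

    calls <- call_enzyme_directions(data, g, attr(cmp, "group_exp"),
                                    attr(cmp, "group_ctrl"), comparison = cmp)
    put(calls, "enzyme_calls.csv")
    prot <- significant_index_proteins(cmp)
    if (nrow(prot)) {
      req <- build_string_request(prot$protein,
                                  path = file.path(out_dir, "string_request.json"))
    } else {
      jsonlite::write_json(list(note = "no significant indices; no seed proteins"),
                           file.path(out_dir, "string_request.json"), auto_unbox = TRUE)
      req <- NULL
    }
    paths[["string_request.json"]] <- file.path(out_dir, "string_request.json")
    res <- c(res, list(enzyme_calls = calls, proteins = prot, string_request = req))
  } else {
    cmp <- compare_indices(im, g, p_threshold = p_threshold)
    put(cmp, "functional_summary.csv")
    res <- c(res, list(comparison = cmp))
  }

  cors <- index_correlations(im)
  put(cbind(data.frame(index_id = rownames(cors)), as.data.frame(cors)),
      "correlations.csv")

  scaled <- scale_index_matrix(im, scaling)
  pca <- index_pca(scaled)
  put(cbind(data.frame(sample_id = pca$sample_id), as.data.frame(pca$scores)),
      "scores.csv")
  put(cbind(data.frame(index_id = rownames(pca$loadings)), as.data.frame(pca$loadings)),
      "loadings.csv")
  put(data.frame(component = seq_along(pca$explained), explained = pca$explained),
      "explained.csv")
  pls <- index_plsda(scaled, g)
  put(data.frame(index_id = names(pls$vip), vip = unname(pls$vip)), "vip.csv")
  put(cbind(data.frame(sample_id = pls$sample_id, group = pls$groups),
            as.data.frame(pls$scores)), "plsda_scores.csv")

  hm <- index_heatmap(scaled, distance = distance, linkage = linkage)
  put(cbind(data.frame(sample_id = rownames(hm$matrix)), as.data.frame(hm$matrix)),
      "heatmap_matrix.csv")
  put(data.frame(step = seq_len(nrow(hm$sample_clust$merge)),
                 left = hm$sample_clust$merge[, 1],
                 right = hm$sample_clust$merge[, 2],
                 height = hm$sample_clust$height),
      "heatmap_sample_merges.csv")
  put(data.frame(step = seq_len(nrow(hm$index_clust$merge)),
                 left = hm$index_clust$merge[, 1],
                 right = hm$index_clust$merge[, 2],
                 height = hm$index_clust$height),
      "heatmap_index_merges.csv")
  res <- c(res, list(correlations = cors, pca = pca, plsda = pls, heatmap = hm))

  if (write_plots && n_groups == 2) {
    ggplot2::ggsave(file.path(out_dir, "summary_bars.png"),
                    plot_index_summary(res$comparison), width = 8, height = 6, dpi = 120)
    ggplot2::ggsave(file.path(out_dir, "volcano.png"),
                    plot_volcano(res$comparison), width = 9, height = 4, dpi = 120)
    ggplot2::ggsave(file.path(out_dir, "dominance.png"),
                    plot_dominance(res$dominance), width = 5, height = 4, dpi = 120)
    ggplot2::ggsave(file.path(out_dir, "pca_scores.png"),
                    ggplot2::autoplot(pca, groups = g), width = 6, height = 5, dpi = 120)
  }

  log_lines <- c(
    paste0("lipidfun version: ", as.character(utils::packageVersion("lipidfun"))),
    paste0("seed: ", seed),
    paste0("p_threshold: ", p_threshold),
    paste0("fc_threshold: ", fc_threshold),
    paste0("scaling: ", scaling),
    paste0("distance: ", distance),
    paste0("linkage: ", linkage),
    paste0("groups: ", paste(unique(g$group), collapse = ", ")),
    paste0("n_samples: ", nrow(g)),
    paste0("n_lipid_rows: ", nrow(data)),
    paste0("n_skipped_rows: ", attr(im, "n_skipped")),
    paste0("indices_not_evaluated: ",
           paste(attr(im, "not_evaluated"), collapse = ", "))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  paths[["run_log.txt"]] <- file.path(out_dir, "run_log.txt")

  invisible(c(res, list(paths = paths, out_dir = out_dir)))
}
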