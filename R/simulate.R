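# Synthetic lipidomics studies with planted, closed-form index effects.
#
# Abundances are lognormal around fixed per-species base means spanning
# about three orders of magnitude (the typical dynamic range between, say,
# PC and gangliosides), so ratio indices are exercised across scales. A
# planted effect multiplies the species matched by the target index's
# numerator selector by 2^delta in the experimental group only; because
# every library denominator is disjoint from its numerator, the expected
# index log2 fold change equals delta exactly, at any noise level.

.species_pool <- function() {
  tibble::tribble(
    ~lipid, ~base,
    "PC 16:0/18:1", 60, "PC 16:0/20:4", 40, "PC 18:0/22:6", 25,
    "PC 34:1", 30, "PC O-16:0/18:1", 8, "PC P-16:0/20:4", 5,
    "PC 16:0/20:4;O", 0.5,
    "LPC 16:0", 4, "LPC 18:1", 2.5, "LPC O-16:0", 0.8, "LPC P-18:0", 0.4,
    "PE 16:0/20:4", 20, "PE 18:0/22:6", 15, "PE 36:2", 10,
    "PE P-16:0/20:4", 6, "PE P-18:0/22:6", 4, "PE O-16:0/18:1", 3,
    "LPE 18:0", 1.5, "LPE 16:0", 1.0, "LPE O-16:0", 0.3, "LPE P-16:0", 0.2,
    "PS 18:0/18:1", 12, "PS 36:1", 8,
    "PI 18:0/20:4", 14, "PI O-18:0/20:4", 1.2,
    "PG 16:0/18:1", 5, "PA 16:0/18:1", 2,
    "SM 34:1;O2", 30, "SM 42:2;O2", 18, "SM 18:1;O2/16:0", 12,
    "Cer 18:1;O2/16:0", 3, "Cer 18:1;O2/24:1", 2.2, "Cer 42:1;O2", 1.5,
    "TG 16:0_18:1_18:2", 70, "TG 16:0_16:0_18:1", 50, "TG 52:2", 40,
    "TG 18:1_18:1_18:2", 35,
    "DG 16:0/18:1", 6, "DG 34:1", 4,
    "CE 18:2", 25, "CE 16:0", 15,
    "CL 72:8", 7, "CL 18:2_18:2_18:2_18:2", 5,
    "CAR 16:0", 0.9, "CAR 18:1", 0.7, "CAR 12:0", 0.25, "CAR 8:0", 0.12,
    "BMP 18:1_18:1", 0.6,
    "FA 16:0", 10, "FA 18:1", 12, "FA 18:2", 8, "FA 15:0", 0.5,
    "FA 17:0", 0.4, "FA 18:3", 1.5, "FA 20:4", 2.5, "FA 22:6", 2.0,
    "FA 22:4", 0.8,
    "GM2 36:1;O2", 0.15, "GM3 36:1;O2", 0.35,
    "Chol", 45
  )
}

.effect_targets <- function(effects, records, library) {
  lapply(seq_len(nrow(effects)), function(i) {
    def <- library[library$index_id == effects$index_id[i], ]
    if (nrow(def) != 1) stop("unknown index in effect spec: ", effects$index_id[i], call. = FALSE)
    sel <- def$num_selector[[1]]
    if (sel$kind == "classes") {
      which(.class_member(records, sel$classes, sel$filter) & records$valid)
    } else if (sel$kind == "chains") {
      hits <- vapply(seq_len(nrow(records)), function(j) {
        ch <- records$chains[[j]]
        if (is.null(ch)) return(FALSE)
        agg <- list(mat = matrix(1, nrow(ch)), keys = paste0(ch$carbons, ":", ch$double_bonds),
                    carbons = ch$carbons, db = ch$double_bonds)
        .chain_keys_present(agg, sel)
      }, logical(1))
      which(hits & records$valid)
    } else stop("cannot plant an effect on this index mode", call. = FALSE)
  })
}

#' Generate a synthetic two-group lipidomics study
#'
#' @param effects `NULL` (pure null study) or a data frame with columns
#'   `index_id` and `log2fc`: each target index's numerator species are
#'   multiplied by `2^log2fc` in the experimental group. Effects whose
#'   target species overlap raise an error (contradictory plants).
#' @param n_per_group Samples per group (default 10).
#' @param cv Within-group coefficient of variation of the lognormal species
#'   noise (default 0.2).
#' @param n_lipids Number of species drawn from the head of the template
#'   pool (default: the whole pool, 60 species covering every library class
#'   at both annotation levels).
#' @param seed Integer seed; identical seeds give identical studies.
#' @param group_labels Two labels, experimental first.
#' @return A list of class `fla_study`: `abundance` (tibble, lipid column +
#'   one column per sample), `groups` (`sample_id`, `group`), `effects`,
#'   `seed`.
#' @examples
#' st <- generate_study(effects = data.frame(index_id = "storage_index", log2fc = 1),
#'                      n_per_group = 5, seed = 42)
#' @export
generate_study <- function(effects = NULL, n_per_group = 10, cv = 0.2,
                           n_lipids = NULL, seed = 1,
                           group_labels = c("EXP", "CTRL")) {
  stopifnot(n_per_group >= 3, cv > 0, length(group_labels) == 2)
  pool <- .species_pool()
  if (!is.null(n_lipids)) pool <- utils::head(pool, n_lipids)
  records <- parse_lipid_names(pool$lipid)
  lib <- fla_index_library()

  mult <- rep(1, nrow(pool))
  if (!is.null(effects) && nrow(as.data.frame(effects)) > 0) {
    effects <- tibble::as_tibble(effects)
    targets <- .effect_targets(effects, records, lib)
    seen <- integer()
    for (i in seq_along(targets)) {
      if (!length(targets[[i]]))
        stop("effect on ", effects$index_id[i], " matches no pooled species", call. = FALSE)
      if (length(intersect(seen, targets[[i]])))
        stop("contradictory effects: planted selectors share lipids", call. = FALSE)
      seen <- c(seen, targets[[i]])
      mult[targets[[i]]] <- mult[targets[[i]]] * 2^effects$log2fc[i]
    }
  }

  set.seed(seed)
  n <- n_per_group
  samples <- c(paste0(group_labels[1], "_", seq_len(n)),
               paste0(group_labels[2], "_", seq_len(n)))
  group <- rep(group_labels, each = n)
  sdlog <- sqrt(log1p(cv^2))
  noise <- matrix(stats::rlnorm(nrow(pool) * 2 * n, meanlog = -sdlog^2 / 2, sdlog = sdlog),
                  nrow = nrow(pool))
  A <- pool$base * noise
  A[, group == group_labels[1]] <- A[, group == group_labels[1]] * mult
  colnames(A) <- samples

  structure(list(
    abundance = tibble::as_tibble(cbind(tibble::tibble(lipid = pool$lipid),
                                        tibble::as_tibble(A))),
    groups = tibble::tibble(sample_id = samples, group = group),
    effects = effects, seed = seed
  ), class = "fla_study")
}

#' Fixed worked toy study
#'
#' A deterministic two-group study (30 species, 3 samples per group)
#' exercising every index computation mode: class fractions and ratios,
#' chain-level ratios, the double-bond weighted mean, chain-matched lyso
#' ratios, a sum-composition species (chain indices' NA path), an oxidized
#' PC and all three ether linkages. Within each group samples differ only by
#' a global scale factor, so every index is exactly constant within group
#' (scale invariance) and all expected values can be computed by hand from
#' the base abundances below.
#'
#' Experimental-group multipliers: TG x2, Cer x1.6, lysophospholipids
#' (LPC/LPE and ether forms) x0.5. The `effects` field records the nominal
#' planted log2 fold changes of three headline indices; realized index
#' shifts differ slightly where a denominator shares perturbed species (the
#' Storage Index moves by about 1.006 rather than exactly 1, because the
#' lyso and ceramide multipliers also touch Total − TG).
#'
#' @return A list of class `fla_study` (see [generate_study()]).
#' @export
toy_lipidomics_study <- function() {
  base <- c(
    "PC 16:0/18:1" = 60, "PC 16:0/20:4" = 40, "PC 34:1" = 30,
    "PC O-16:0/18:1" = 8, "PC P-16:0/20:4" = 5, "PC 16:0/20:4;O" = 0.5,
    "LPC 16:0" = 4, "LPC O-16:0" = 0.8,
    "PE 16:0/20:4" = 20, "PE 18:0/22:6" = 15, "PE P-16:0/20:4" = 6,
    "LPE 18:0" = 1.5, "LPE P-16:0" = 0.2,
    "PS 18:0/18:1" = 12, "PI 18:0/20:4" = 14, "PG 16:0/18:1" = 5,
    "PA 16:0/18:1" = 2, "SM 34:1;O2" = 30, "Cer 18:1;O2/16:0" = 3,
    "TG 16:0_18:1_18:2" = 70, "TG 52:2" = 40, "DG 16:0/18:1" = 6,
    "CE 18:2" = 25, "CL 72:8" = 7, "CAR 16:0" = 0.9,
    "BMP 18:1_18:1" = 0.6, "FA 18:1" = 12,
    "GM2 36:1;O2" = 0.15, "GM3 36:1;O2" = 0.35, "Chol" = 45)
  exp_mult <- rep(1, length(base))
  names(exp_mult) <- names(base)
  exp_mult[startsWith(names(base), "TG ")] <- 2
  exp_mult[startsWith(names(base), "Cer ")] <- 1.6
  exp_mult[grepl("^LP[CE]", names(base))] <- 0.5
  ctrl_f <- c(1, 1.08, 0.94)
  exp_f <- c(1.02, 0.97, 1.05)
  A <- cbind(base %o% ctrl_f, (base * exp_mult) %o% exp_f)
  samples <- c(paste0("CTRL_", 1:3), paste0("EXP_", 1:3))
  colnames(A) <- samples
  structure(list(
    abundance = tibble::as_tibble(cbind(tibble::tibble(lipid = names(base)),
                                        tibble::as_tibble(A))),
    groups = tibble::tibble(sample_id = samples,
                            group = rep(c("CTRL", "EXP"), each = 3)),
    effects = tibble::tibble(index_id = c("storage_index", "cer_sm", "lpc_pc"),
                             log2fc = c(1, log2(1.6), -1)),
    seed = NA_integer_
  ), class = "fla_study")
}
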