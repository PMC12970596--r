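---
title: "Functional lipid indices: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional lipid indices: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidfun)
```

## The model

`lipidfun` replaces the species-level view of a lipidome with a panel of 42
functional indices, each a ratio or weighted sum over lipid classes,
molecular species, or fatty acyl/alkyl/alkenyl chains. The design premise is
that ratios of co-measured quantities are robust to the global scale of a
sample — extraction efficiency, injection volume, total lipid load — so every
index is invariant under multiplication of a sample's abundances by any
positive constant (this is enforced by a property test). Indices come in five
computation modes:

- **class fraction** — X / (Total − X), e.g. the Storage Index (TG);
- **class ratio** — X / Y over disjoint class sets, e.g. PE/PC;
- **chain ratio** — computed on the chain-level abundance table, where every
  resolved chain of every species contributes that species' abundance (a TG
  contributes three chain entries), e.g. Saturation Index, n-6/n-3;
- **double-bond weighted mean** — Σ(abundance × DB)/Σ(abundance) over all
  species with a defined DB count;
- **chain-matched lyso ratio** — lyso species counted only when their single
  chain occurs among the resolved chains of an intact partner class, and
  intact species only when one of their chains occurs as a lyso; computed
  separately for ester, ether (O-) and plasmalogen (P-) linkages.

### Missing values are information

An index is `NA` for a sample when its denominator is zero, when no measured
species matches its numerator selector, or when it requires resolved chains
and the dataset has none. `NA` is a value, never an error, and zeros are kept
as zeros — no pseudocounts. We prefer an honest `NA` over imputation because
zero-handling can silently inflate ratio statistics at low abundance;
downstream functions carry explicit `comparable`/`n_evaluated` bookkeeping so
that missingness never biases a summary. Eleven indices require resolved
chains (the seven chain ratios, the three matched lyso ratios, and the
ferroptosis index); they switch off automatically on sum-composition-only
datasets, while the Double Bond Index and PC Unsat/Sat intentionally operate
on species-level DB counts so they survive sum-composition annotation.

## Nomenclature conventions

The parser accepts LIPID MAPS shorthand at both annotation levels
(`PC 34:1`, `PC 16:0/18:1`, `_` and `/` separators) plus the ether dialects
`PC O-34:2`, `PC O 34:2` and `PC-O 34:2`, case-insensitively. Conventions
that the shorthand leaves open were fixed as follows:

- A bare class token in an index formula means the **ester (diacyl)** form;
  ether and plasmalogen species are separate tokens (`PC O`, `PC P`). This
  keeps the ether-lipid and plasmalogen indices disjoint from their diacyl
  counterparts.
- A `;O`/`;On` suffix marks **oxidation** only on glycerophospholipids; on
  sphingolipids (SM, Cer, GM2, GM3) and sterols it is backbone hydroxylation
  and part of the canonical name. The OxPL index is restricted to
  non-ether PC/PE/PG/PI/PS accordingly.
- Free cholesterol is class `Chol` (aliases `Cholesterol`, `ST 27:1;O`);
  cholesteryl esters are a distinct class with their own index.
- Where a formula says "PL" without enumeration (DG/PL, PA/PL, TG/PL,
  (LPC+LPE)/PL, PL/SM), PL = {PC, PE, PG, PI, PS}, matching the one place the
  set is spelled out.
- Unparseable rows are skipped with a logged count; a run aborts only when
  more than half the rows fail, which almost always indicates a wrong input
  orientation rather than a few exotic species.

Decisions for formula details the panel leaves open: chain-length bins are
short C2–C9, medium C10–C15, long C16–C25 (conventional biochemistry bins);
saturation and MUFA/PUFA splits are chain-level (DB = 0 vs ≥ 1, DB = 1 vs
≥ 2); odd/even parity uses resolved chains only, because the parity of a
multi-chain sum composition is ambiguous; AA/DHA and n-6/n-3 are defined
purely by the C:DB keys of esterified chains across all classes — the
shorthand cannot encode ω-position, so none is inferred; the ferroptosis
index follows the narrower PE + PE P definition (species carrying 20:4, 22:4
or 22:6); the GM3/GM2 ratio applies its "both detected" rule per sample; the
Double Bond Index uses the nominal DB count written in the name (the
plasmalogen vinyl ether bond is not added), keeping the index reproducible
from names alone.

## Statistics

Two-group comparison uses Welch's unequal-variance t test per index, with
unadjusted p-values by default: the panel is small (≤ 42 pre-defined,
correlated-by-construction indices), so raw p-values with an optional
Benjamini–Hochberg column (`adjust = TRUE`) are more interpretable than a
default correction. The effect size is log2(m₁/m₂) of group means with a
delta-method standard error

SE = (1/ln 2) · sqrt( s₁²/(n₁·m₁²) + s₂²/(n₂·m₂²) ),

which is distribution-light and coherent with the Welch test; the acceptance
suite verifies it against a 10,000-replicate bootstrap. Default thresholds
are p < 0.05 and |log2FC| ≥ 1, both user-configurable. Functional dominance
aggregates Σ|log2FC| of significant indices per category, normalised by the
number of indices actually evaluated there, so missing indices cannot
deflate a category. Biomarker ranking orders by p, then polarity-corrected
AUC (max(AUC, 1−AUC), computed from the Mann–Whitney rank statistic with
midranks), then |Cohen's d| (pooled-SD form) — the ordering itself is a
package choice, since the metrics panel has no canonical order. Post-hoc
power is the exact noncentral-t power of the two-sample t test at the
observed |d| and group sizes. With more than two groups, each index gets a
Welch one-way ANOVA (F test, no fold change). Degenerate inputs are handled
deliberately: two numerically constant equal groups give t = 0, p = 1; a
constant index gets AUC 0.5 and d = 0 and ranks last.

## Multivariate analysis

PCA (SVD) and PLS-DA both run on the completed, scaled index matrix:
indices with more than 20% missing values are dropped, the remainder
median-imputed, and columns centred and auto-scaled by default (center-only
and Pareto options exist). Auto-scaling is also applied before PLS-DA so the
two projections see the same matrix. PLS-DA is a PLS2 fit on one-hot group
labels (via mixOmics) with 2 components by default, matching 2-D score
plots with 95% Hotelling T² ellipses; VIP scores satisfy Σ VIP² = p
identically, which the tests assert for every fit. The heatmap offers seven
distance measures — euclidean, manhattan, chebyshev, canberra, minkowski
(p = 3), correlation (1 − r) and spearman (1 − ρ) — with complete (default),
average, single or Ward linkage; the exact seven-member set is a package
choice and is fixed so that results are comparable across runs.

## From indices to enzymes

Each index carries a curated list of human proteins that catalyse, regulate
or consistently respond to its lipids; significant indices contribute their
lists (with provenance) to the seed set of an offline STRING request
payload (network type full/physical, confidence 0–1000, neighbour count,
eight annotation sources). Direction calls come from a small curated
reaction table (16 reactions over the panel's recurrent enzymes; acyl-CoA
substrates are proxied by free fatty acids, and completeness is explicitly
not claimed): for each reaction the group-mean product sum over group-mean
substrate sum is compared between groups as a ratio test with a 10% relative
tolerance — chosen so that calls flip exactly under a group swap — and any
zero sum yields `indeterminate`. These are stoichiometric hypotheses, not
kinetics: no protein concentration or flux is estimated.

## The synthetic-study generator

`generate_study()` emulates a two-group lipidomics study: 60 template
species covering every class of the panel at both annotation levels, with
class-level base abundances spanning about three orders of magnitude (PC and
TG tens of units, gangliosides fractions of a unit), lognormal within-group
noise at CV = 0.2, and 10 samples per group by default — sizes typical of a
cell-biology lipidomics experiment. A planted effect multiplies the species
matched by the target index's numerator selector by 2^δ in the experimental
group; because every numerator is disjoint from its denominator, the
expected index log2FC equals δ exactly at any noise level, which gives the
recovery tests a closed-form truth. The generator does **not** simulate
instrument artifacts (in-source fragmentation, isotopes, adducts), missing
not-at-random species, or class-correlated noise, so passing tests demonstrate
correctness of the computation and calibration of the statistics on clean
compositional data — not robustness to acquisition artifacts in real
datasets.

The fixed worked toy study (30 species, 3 + 3 samples) uses purely
multiplicative sample factors so every index is exactly constant within
group and every expected value can be computed by hand; it deliberately
exercises the oxidized-PC, ether, plasmalogen, sum-composition and
chain-matched code paths, and leaves four indices (odd/even, PC unsat/sat,
long/medium, short/long) unevaluated to exercise the NA bookkeeping.

## Problem sizes and numerical choices

The test and acceptance workloads use 1,000 simulated null studies for the
type-I error check (binomial 99% CI around α = 0.05), 500 replicate studies
for planted-effect recovery (|bias| < 0.05, top-20 rate > 95%), a
10,000-replicate bootstrap for the SE check, and 200 random profiles against
a brute-force summation oracle at 1e-12 relative tolerance — sizes at which
the Monte-Carlo error is comfortably below each tolerance. CSV output is
written with 6 significant digits and the literal `NA`, which makes pipeline
runs byte-identical and lets a golden-file test pin the full result bundle.

## Limitations

Index coverage depends on annotation depth: sum-composition datasets yield a
reduced panel. Several indices are correlated by construction and should be
read as a panel, not as independent tests. Protein mappings are curated for
human; applying them to other organisms is left to the user. The reaction
table is minimal and the direction calls are hypothesis-generating only.
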