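# lipidfun

Functional lipid indices from quantitative lipidomics.

Lipidomics experiments quantify hundreds of individual lipid species, but the
biology usually acts at the level of *functions*: membrane structure and
fluidity, energy storage and mobilization, and lipid signaling. `lipidfun`
condenses a lipid abundance matrix (species in LIPID MAPS shorthand × samples)
into a curated panel of **42 biochemically defined functional indices** —
ratios and weighted sums over lipid classes, molecular species and fatty
acyl/alkyl/alkenyl chains — and then treats those indices as the variables for
all downstream statistics. It is written for lipidomics analysts who want
directional, mechanistically interpretable readouts rather than species lists
or enrichment tables.

## The panel

Each index reads out one function. Examples, in the field's notation:

- **Storage Index** = TG / (Total − TG); **Energy Load** = (TG + DG + CE) / (Total − TG − DG − CE)
- **Double Bond Index** = Σ(abundance × DB) / Σ(abundance) — mean double bonds
  per molecule, a membrane-fluidity proxy
- **Cer/SM** = Ceramide / Sphingomyelin — the sphingomyelinase stress axis
- **Saturation Index** = saturated / unsaturated acyl chains (chain-level)
- **n-6/n-3** = (18:2 + 20:4) / (18:3 + 22:6) esterified chains
- **Lyso/PL (matched)** = (LPC + LPE) / (PC + PE) restricted to chain-matched
  lyso–intact pairs, in ester, ether (O-) and plasmalogen (P-) flavours
- **Ferroptosis Susceptibility** = PE and PE P species carrying 20:4/22:4/22:6
  over the rest of the lipidome

The panel spans three categories (15 Structural, 17 Signaling, 10 Energy).
Indices are compared between groups with Welch's t test; the log2 fold change
of group means gets a first-order error-propagation (delta-method) standard
error, SE = (1/ln 2)·√(s₁²/(n₁m₁²) + s₂²/(n₂m₂²)). Per-category **functional
dominance** sums |log2FC| of significant indices over the number evaluated.
Biomarker ranking reports polarity-corrected ROC AUC (max(AUC, 1−AUC)),
Cohen's d and noncentral-t post-hoc power. PCA, PLS-DA with VIP scores
(Σ VIP² = number of indices), and hierarchical clustering over seven distance
measures operate on the index matrix. Each index also carries a curated human
protein list; significant indices seed an offline STRING network request, and
a small curated reaction table turns group-wise product/substrate balances
into enzyme direction calls (forward-increased / forward-decreased /
indeterminate).

Values are `NA` — never an error — when an index's denominator is zero or its
required species/chains are absent; sum-composition-only datasets
automatically disable the chain-resolved indices.

## Worked example

`toy_lipidomics_study()` is a fixed 30-species, 2×3-sample study in which the
experimental group has TG doubled, ceramide ×1.6 and lysophospholipids halved:

```r
library(lipidfun)
st  <- toy_lipidomics_study()
im  <- compute_index_matrix(st$abundance)       # 6 samples × 42 indices
cmp <- compare_indices(im, st$groups, group_exp = "EXP", group_ctrl = "CTRL")
dplyr::filter(cmp, significant) |>
  dplyr::select(index_id, log2fc, p_value, auc)
#>   index_id       log2fc p_value   auc
#> 1 lyso_pl         -1          0     1
#> 2 lpc_pc          -1          0     1
#> 3 lyso_o_matched  -1          0     1
#> 4 lyso_p_matched  -1          0     1
#> 5 lyso_matched    -1          0     1
#> 6 storage_index    1.01       0     1
#> 7 tg_ce            1          0     1
#> 8 tg_fa            1          0     1
#> 9 tg_pl            1          0     1

functional_dominance(cmp)
#>   category   dominance n_evaluated n_significant
#> 1 Structural     0              13             0
#> 2 Signaling      0.294          17             5
#> 3 Energy         0.501           8             4
```

The planted lipolysis/storage phenotype is read out exactly: every TG ratio
index moves by +1 log2 unit, the matched lyso ratios by −1, and the dominance
panel flags Energy and Signaling, not Structural. Mapping the significant
indices to proteins puts DGAT1 and LPL at the top (4 supporting indices each),
and the reaction-balance module calls DGAT1/DGAT2 forward-increased and
PLA2G4A forward-decreased — the enzyme-level mirror of the planted effects.

The whole workflow, with CSV/JSON outputs, is one call:

```r
run_fla_pipeline(st, out_dir = "results_toy",
                 group_exp = "EXP", group_ctrl = "CTRL")
```

or from a shell via the thin wrapper `inst/cli/lipidfun.R`
(`simulate` and `run` verbs).

## Scope notes

Protein lists ship for human; the organism field in STRING requests is
reserved. The STRING payload is built offline — no network call is made. The
package does not infer chain compositions for sum-composition species and
does not estimate enzyme kinetics; direction calls are hypotheses derived
from curated reaction stoichiometry.
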