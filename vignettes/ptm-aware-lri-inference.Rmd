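---
title: "PTM-aware ligand-receptor inference: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PTM-aware ligand-receptor inference: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmlri)
```

## The problem

Cell-cell communication is commonly inferred from expression data alone: a
ligand and a receptor are both regulated, and proteins downstream of the
receptor in some pathway move with them. Expression, however, misses the
regulatory layer that actually switches many pathways on and off:
post-translational modifications (PTMs). A receptor can be abundant yet
inactive because its activation loop is not phosphorylated; a transcription
factor can be abundant yet headed for degradation because it is
ubiquitinated. `ptmlri` infers ligand-receptor interactions (LRIs) from
two-cluster differential proteomics and then refines every inference with
site-level PTM evidence checked against a direction-aware PTM-pathway
reference.

## Reference data model

Four tables drive the inference:

* **LR pairs** - curated ligand-receptor couples.
* **Pathways** - named protein sets (e.g. from a pathway database or
  user-defined).
* **Intracellular network** - a partially directed protein-protein edge
  list. Directed edges are traversed forward only; undirected edges both
  ways.
* **PTM reference records** - `(protein, residue, position, type,
  direction, enzyme, pathway)` rows stating that, within a pathway, an
  enzyme adds (`added`) or removes (`removed`) a specific modification at a
  specific residue.

**Receptor targets** within a pathway are the proteins reachable from the
receptor in the pathway-restricted network (`receptor_targets()`), receptor
excluded. Reachability treats every reachable protein as a target; the
model does not distinguish intermediary signaling proteins from endpoints,
because the downstream statistic only asks whether proteins controlled by
the receptor move together. Pathways are kept when they offer at least
`min_targets` (default 5; rank statistics on fewer targets are unstable)
and at most `max_members` (default 400; very large sets dilute specificity)
members.

### Building the PTM reference from reactions

`build_ptm_reference()` consumes a neutral JSON export of biochemical
reactions (inputs, outputs, catalysts, pathway annotations). For each
protein, modification states are pooled per reaction side (multiple
occurrences of a protein on one side have their modification sets unioned -
a conservative choice, since the export does not define multiplicity) and
diffed: a site present only on the product side is an `added` event, one
present only on the reactant side a `removed` event. Each diffed site is
expanded against every catalyst and every annotated pathway. Reactions
flagged as tentative ("candidate") are excluded, and entities in complexes
of more than `max_complex_size = 10` proteins are ignored - *more than*,
i.e. a complex of exactly 10 is retained. Reactions without pathway
annotation are emitted under `UNASSIGNED` and dropped at bundle load, so no
information is silently lost before the integrity check. A live
graph-database query would be needed to regenerate a full-scale reference;
the package deliberately takes the JSON export as its input so the builder
is testable offline.

## Statistical model

For two sample clusters A and B:

1. **Per-row differential testing.** Every protein (and every normalized
   PTM site) gets `delta = median(B) - median(A)` and a two-sided Wilcoxon
   rank-sum p-value (`wilcoxon_two_sided()`). The test is pluggable; the
   Wilcoxon default uses the exact null distribution when both sides have
   at most 25 observations and no ties, and the tie-corrected normal
   approximation with continuity correction otherwise. A constant row has
   p = 1 by convention (the zero-variance normal approximation is
   indeterminate). Medians are used for `delta` because they pair naturally
   with a rank test; means are available via the `summary` argument.

2. **PTM normalization.** Site intensities are normalized by the parent
   protein's abundance in the same sample (`normalize_ptm()`): `ratio` mode
   divides (the default, suited to linear-scale data; non-positive protein
   values make the cell missing), `difference` mode subtracts (suited to
   log-scale data). The resulting quantity is a relative, per-protein
   measure of modification, not an absolute stoichiometry. Sites whose
   parent protein is not detected in the expression matrix are discarded:
   PTM information is complementary evidence for pathways already supported
   by expression.

3. **Pathway significance by rank statistic.** Not all targets of a true
   pathway respond, so pathway evidence is summarized by a rank statistic
   of the sorted target p-values: with order statistics
   $p_{(1)} \le \dots \le p_{(n)}$,
   $$T = \min_k F_{\mathrm{Beta}(k,\,n-k+1)}\!\left(p_{(k)}\right),$$
   the most surprising order statistic measured on the scale of the uniform
   null (the k-th order statistic of n uniforms is Beta(k, n-k+1)). T is
   not itself uniform, so it is calibrated by Monte Carlo
   (`rank_statistic_pvalue()`): `n_mc` draws (default 10,000, minimum
   1,000) of n uniforms under a fixed seed, with a +1/+1 continuity rule so
   the estimate is never zero. Null draws are cached per (n, n_mc, seed),
   and the seed is echoed in the run metadata. The exact functional form of
   a rank statistic is a design choice of this package: it is a genuine
   rank statistic of the sorted target p-values, well calibrated by
   construction, and testable against an independent Monte-Carlo oracle.

4. **Combining evidence.** The overall LRI score is the plain product
   $p_L \cdot p_R \cdot p_{\mathrm{pathway}}$, assuming independence for
   simplicity; it is reported as `p_overall`. A product of three uniforms
   is far from uniform ($P(\mathrm{prod} \le 0.05) \approx 0.42$), so
   thresholding the raw product would select roughly 10% of null triples
   even after sign constraints. Selection therefore uses the product's
   exact null calibration (`calibrate_product()`; Fisher's method:
   $-\ln \mathrm{prod} \sim \Gamma(k, 1)$ for k independent uniform
   factors), reported as `p_overall_cal`, with Benjamini-Hochberg
   correction across all scored triples (`q_value`). This is the one place
   the package deliberately departs from thresholding the printed product;
   without it, no nominal threshold controls the null selection rate.

5. **Sign constraints.** The ligand must increase in cluster B (triples
   with `ligand_delta <= 0` are removed). The receptor is required positive
   by default; `receptor_sign = "negative"` selects inhibitory regulation
   instead. Target signs are free by default; `target_sign = "positive"`
   replaces wrong-signed targets' p-values by 1 before the rank statistic.

6. **PTM refinement.** For each scored triple, every reference record of
   its pathway becomes an observed event when the substrate is detected in
   the expression data, the annotated enzyme is detected too (or the record
   has no enzyme), and the site was tested. Events carry the site's delta
   and p-value and a concordance call: `added` with a positive delta (e.g.
   increased phosphorylation downstream of a kinase) or `removed` with a
   negative one is `concordant`; opposite signs are `discordant`; zero or
   missing deltas are `indeterminate`. Discordant events are *kept and
   flagged* - reference databases contain errors and regulation can be more
   complex than a single enzyme - and a site annotated both `added` and
   `removed` in one pathway simply yields two events, with no
   reconciliation. Event p-values feed the same calibrated rank statistic,
   giving `p_ptm_pathway` (missing when a triple has no usable event), BH
   corrected as its own family (`q_ptm`) separate from the expression
   family, mirroring the two output columns.

7. **Selection.** In the default `dual_threshold` mode a triple is selected
   when its expression statistic passes `alpha_expr = 0.05`
   (`expression_only`, upgraded to `ptm_confirmed` when the PTM statistic
   also passes `alpha_ptm = 0.05`), **or** when it only passes the relaxed
   threshold `alpha_expr_relaxed = 0.25` but the PTM statistic is
   significant (`ptm_rescued`). The rescue rule realizes "an LRI that is
   not significant on expression alone can be predicted with greater
   confidence by significant PTM regulation"; the 0.25 default is a design
   choice (no published numeric rule exists), and setting
   `alpha_expr_relaxed = alpha_expr` disables rescue. `selection_mode =
   "product"` instead multiplies the PTM statistic in as a fourth factor,
   recalibrates, and thresholds at `alpha_expr`. By default thresholds
   apply to the BH-adjusted statistics (`use_adjusted = TRUE`); set it to
   `FALSE` to threshold the calibrated raw statistics.

8. **Global protein mode.** `ptm_position_mode = "protein"` replaces, per
   (protein, modification type), every site's statistics by the most
   extreme site's (smallest p; ties broken by larger |delta|, then by
   lexicographically smallest site key - deterministic and idempotent).

## Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `min_targets` / `max_members` | 5 / 400 | pathway size window |
| `alpha_expr` | 0.05 | expression selection threshold |
| `alpha_expr_relaxed` | 0.25 | expression threshold under PTM rescue |
| `alpha_ptm` | 0.05 | PTM selection threshold |
| `n_mc` | 10,000 | Monte-Carlo draws for rank-statistic calibration |
| `exact_threshold` | 25 | max per-side n for exact Wilcoxon |
| `ptm_normalization` | `ratio` | parent-protein normalization mode |
| `max_complex_size` | 10 | complex-size cutoff in the reference builder |

## The synthetic-data generator

`simulate_bundle()` / `simulate_matrices()` state a simple world: pathway j
contains receptor Rj, kinase Kj and `targets_per_pathway` targets wired
R -> K -> targets; each pathway gets one LR pair and
`ptm_sites_per_pathway` phosphorylation reference records (alternating
added/removed, catalysed by Kj). Intensities are log-scale Gaussians
(`baseline_mean = 20`, `baseline_sd = 1`, a typical log2 MS intensity
scale); 20 + 20 samples; planted triples (default 1 of 10 pathways) shift
ligand, receptor and targets by `effect_size = 3` standard deviations in
cluster B - a strong but realistic change for a truly regulated protein.
PTM site rows equal the parent protein's value plus an independent site
term, so difference-mode normalization *exactly* isolates the planted
site-level effect, making parameter recovery analytically transparent;
ratio mode is exercised by exponentiating. Planted site shifts match the
reference direction for a `frac_concordant` share (default 1) and oppose it
otherwise; 5% of cells are missing.

What the generator does **not** emulate: reporter-ion chemistry and batch
structure of labeled MS experiments, intensity-dependent missingness,
correlated noise across proteins, isoforms, or the heavy-tailed abundance
distributions of real proteomes. A green end-to-end test therefore
establishes that the statistical machinery recovers planted signal at
stated sizes and stays quiet under the null - not that the method's
biological error rates on real cohorts match.

## Numerical choices and degenerate inputs

* Monte-Carlo p-values use the +1/+1 rule and never return 0; the smallest
  attainable value is 1/(n_mc + 1).
* Score-based clustering (`assign_clusters_by_score()`) uses type-7
  quantiles; a sample falling in both tails (over-discrete scores) is fatal
  rather than silently resolved.
* Empty sides after missing-value removal give a missing p-value and the
  row is excluded downstream; a triple whose ligand or receptor lacks a
  test result is dropped and logged; a pathway with no measured target
  cannot be scored and its triples are dropped.
* Symbols are upper-cased on load; undirected edges are stored once with
  canonically ordered endpoints; duplicate records are dropped with logged
  counts; PTM records referencing unknown pathways are dropped with a
  warning.
* All tables are plain TSV; every writer has a reader and the pair is a
  fixpoint. Config files are JSON (this package does not depend on a YAML
  parser), and every run writes a config echo plus the seed in
  `meta.json`.

## Known limitations

* The PTM reference shipped by a user is only as good as its source;
  reference errors surface as discordant events rather than being removed.
* The overall score combines component p-values under an independence
  assumption that is only approximate (ligand, receptor and targets share
  samples).
* Correlation-based inference (as opposed to two-cluster differential
  mode) is out of scope, as are single-cell-specific preprocessing and
  deconvolution-based composition scores: cluster labels or a per-sample
  score are taken as given.
* p-values from the discrete Wilcoxon null are conservative at very small
  sample sizes; with fewer than ~4 samples per side the smallest attainable
  p-value is large and power is limited by the test, not the pipeline.
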