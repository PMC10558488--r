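---
title: "Methods: cofactor stoichiometry and enzyme decline in cancer cachexia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cofactor stoichiometry and enzyme decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Cancer cachexia is an involuntary wasting syndrome in which skeletal muscle
and body weight are lost despite nutritional support. Multi-omics profiling
of cachectic mouse livers points to a characteristic lesion: enzymes that
depend on B-vitamin cofactors (NAD from niacin, pyridoxal phosphate from
vitamin B6, coenzyme A from pantothenate, FAD/FMN from riboflavin) are
disproportionately lost, and the more abundant the enzyme, the stronger its
decline. Because cofactor metabolites and their enzymes sit near a one-to-one
molar stoichiometry in healthy tissue, a coordinated drop of the enzyme pool
is also a drop of the tissue's cofactor-binding capacity.

`cachexomics` packages the statistical machinery needed to establish and
exercise that chain of reasoning on tabular omics data:

1. **Annotation-driven aggregation** (`evaluate_search_formula()`,
   `build_cofactor_objects()`): free-form boolean formulas over a
   UniProt-style catalog define "cofactor objects" — a named cofactor class
   carrying the summed molarity of its member metabolites and of its member
   enzymes.
2. **Common molar scale** (`tissue_to_molar()`, `proteome_share_to_molar()`,
   `mass_to_molar()`): metabolite amounts per gram of tissue, proteome
   abundance shares, and food-table vitamin masses are all mapped to mM.
3. **Stoichiometry statistics** (`loglog_fit()`, `molar_ratio()`,
   `species_ratio_summary()`): log-log regression of enzyme pools on
   metabolite pools, and the molar ratio with its *gray zone*.
4. **Abundance-dependent decline** (`depression_slope()`,
   `binary_classify()`, `cofactor_regression()`).
5. **Compartment-matched resampling** (`matched_subsample()`,
   `pca_scores()`, `svm_margin()`).
6. **Acyl-PTM competition** (`find_shared_sites()`, `adjust_fc()`,
   `acyl_group_compare()`).
7. **Blood biomarkers** (`jonckheere_trend()`, `rf_mda_select()`,
   `roc_auc()`).
8. **Synthetic data with planted truth** (`generate_*()`), so every stage is
   testable without any external download.

# Models, conventions and tunable parameters

## Preprocessing rules

Metabolome matrices: entities missing in *every* sample are removed
(`drop_all_missing_entities()`), then every remaining missing cell is imputed
with one half of the *global* minimum over all present values of the matrix
(`impute_half_minimum()`) — global, not per-entity, so imputed values sit
below the detection floor of the whole dataset. Proteome matrices are never
imputed; rows containing any missing value are dropped
(`drop_incomplete_proteins()`). TMT-style intensity matrices can be put on a
common scale by median-ratio normalization against a reference channel
(`median_ratio_normalize()`); the scale factor of a sample is the median over
entities of its per-entity ratio to the reference, so normalization is
idempotent.

Fold changes are ratios of arithmetic group means on the linear scale
(experimental over control). A median-based estimator is available
(`estimator = "median"`) because TMT normalization itself is median-based;
means are the default. Welch's unequal-variance two-sided *t*-test supplies
volcano p-values; two exactly identical groups are defined to give p = 1 and
zero-variance groups with different means give p = 0.

## Molar conversions

* Tissue amounts: 1 µmol/g maps to exactly 1 mM under a tissue specific
  gravity of 1.0 g/cm³.
* Proteome shares: an abundance share (or ppm / 10⁶) times an assumed total
  protein concentration of 5 mM; a whole proteome of shares therefore sums to
  exactly 5 mM.
* Food-composition tables: mg per 100 g divided by the vitamin's molecular
  weight, times 10, assuming 100 g of food occupies 100 mL. The molecular
  weights are fixed (`vitamin_mw_table()`): B1 265.355, B2 376.36, NIA
  123.111, B6 169.18, PA 219.23, Biotin 244.31, Folate 441.4, B12 1355.388
  g/mol; derivative heterogeneity is deliberately ignored.

## Search formulas

A formula is a boolean tree over field predicates; the text dialect is
`field:"substring"` (case-insensitive), `field~"regex"` (case-insensitive),
`field="TAG"` (exact membership in a semicolon-separated tag set), combined
with `AND`, `OR`, `NOT` and parentheses. Free-text fields (catalytic
activity, nucleotide binding) default to substring matching because they are
prose; tag fields (keyword ids, ChEBI ids) use exact matching so
`"CHEBI:1"` can never match `"CHEBI:123"`. The shipped formula file
(`default_formula_file()`) is a *reconstruction* keyed on canonical cofactor
ChEBI ids and EC-number presence; every entry is marked `reconstructed: true`
and any catalog/formula pair can be substituted. Cofactor objects may overlap
in membership (a one-carbon enzyme can also be a B6 enzyme); only the
three-way proteome partition (`partition_proteome()`) is mutually exclusive,
with B-vitamin membership taking precedence over "other enzymes".

## Stoichiometry

The gray zone is the closed interval |log₁₀(metabolite mM / enzyme mM)| ≤ 1,
i.e. ratios in [0.1, 10]; the boundary is taken as inclusive ("within ±1" read
as a closed interval — the open reading would change nothing in practice
because boundary ratios have measure zero in real data). Nonpositive values
are excluded from log fits and counted, never offset-shifted. The
cross-species "average" ratio is ambiguous between arithmetic and geometric
readings; the geometric mean (mean of log₁₀ ratios) is primary because ratios
are multiplicative, and the arithmetic mean is emitted alongside.

## Depression slope and regression

The depression slope is the OLS slope of log₂ fold change on log₁₀ molar
concentration, reported ×1000 ("permille"): the log₂-FC change per decade of
abundance, per mille. This definition is recorded in every result object so
alternative conventions remain auditable. The high/low split of the
classification mosaic is computed on log₁₀ concentrations by default (all
concentration axes in this field are logarithmic); a linear-scale mean and a
reference-proteome quartile rule (high = above the external 75th percentile)
are selectable, and the rule used is recorded in the output. Ties at the
threshold go to "low", and log₂ FC exactly 0 is excluded from up/down — a
choice that only matters for degenerate synthetic data. The multiple
regression uses log₂ FC as response and a focal-group dummy plus log₁₀
concentration as predictors; GVIF per predictor is 1/(1 − R²ⱼ), which for two
predictors reduces to 1/(1 − r²) of their correlation for both.

## Matched resampling and SVM margins

Adjusted proteome datasets are drawn without replacement within three
mutually exclusive compartments; the preset counts (96 NIA+B6+C1 enzymes,
292 other enzymes, 669 non-enzymes; 1057 total) mirror the muscle proteome's
composition so liver draws are compartment-matched to muscle. PCA uses
unit-variance scaling; the linear SVM (cost 1, the library default) is fitted
on the PC1/PC2 score plane, where the maximal margin — the shortest Euclidean
distance between the two margin lines — is 2/‖w‖. For non-separable draws the
width is still reported together with the count of margin violations. A
master seed derives per-draw seeds, all of which are returned, so any single
draw can be regenerated. Ties in margin comparisons count as "not greater".

## Acyl-PTM competition

Acetyl-, malonyl- and succinyl-CoA compete non-enzymatically for the same
lysine ε-amines, so sites modified by all three acyl types are informative
about acyl-CoA pool shifts. Shared sites are the exact triple intersection on
(protein, residue position); peptide context is ignored because positional
mapping is assumed resolved upstream. Site fold changes are divided by the
parent protein's fold change ("adjusted FC") to isolate modification-level
change, filtered to the strict open interval (0.03, 32) to drop ratio
artifacts, and compared on the log₂ scale by one-way ANOVA followed by
many-to-one Dunnett contrasts against malonylation as the single control
(multivariate-*t* by default; a permutation max-*t* alternative with a
recorded seed is provided and cross-checked against exhaustive relabeling in
the test-suite). The intersection is computed after filtering by default.

## Blood-biomarker statistics

The Jonckheere–Terpstra statistic sums Mann–Whitney counts over ordered group
pairs (ties = ½); the one-sided p-value is a permutation estimate with the
add-one correction p = (1 + #extreme)/(1 + n_perm), so p is never 0 and never
below 1/(n_perm + 1). The default is 10,000 permutations (configurable and
logged). Random-forest selection repeats 500-tree forests across trials with
distinct derived seeds — full reproducibility is preferred over literally
unseeded trials — and selects features whose mean decrease in accuracy
(permutation importance, z-scaled by its standard error across trees) exceeds
1.5, with a percentile 95% CI across trials. Univariate AUC is the rank
statistic with half-credit ties; multivariate AUC scores a maximum-likelihood
logistic combination.

A calibration note on the MDA threshold: the z-scaled importance of a truly
null feature is approximately standard normal, so a threshold of 1.5 admits
roughly `pnorm(-1.5)` ≈ 6.7% of pure-noise features. The null-calibration
test asserts that measured rate rather than a smaller one; the threshold is a
screening device, not a formal test.

# The synthetic-data generators

The generators emulate the structure of the study conditions, with planted
truth returned beside every dataset:

* `generate_catalog()` — 2,000 proteins by default, assigned to cofactor
  classes (NIA 5%, B6 4%, C1 4%, PA 3%, B2 3%, B1 2%, ATP 8%, SAM 3%, Gly 3%,
  generic other enzymes 25%, the rest non-enzymes), annotated with EC
  numbers, enzyme keywords and canonical cofactor ChEBI ids so the default
  formulas recover the planted classes exactly. Abundances are log-normal
  (log₁₀ mM centred at −3, sd 1, i.e. spanning about six decades as liver
  proteomes do) normalized to a 5 mM total; B-vitamin classes are shifted up
  by 0.5 decades by default, emulating the high hepatic expression of
  B-vitamin enzymes. Half of the C1 enzymes carry a folate tag (B-vitamin
  dependent), half do not.
* `generate_metabolome()` — per cofactor class, the metabolite pool total is
  the enzyme pool total × 10^N(ratio_mean, ratio_sd) with defaults (0, 0.3),
  split randomly over three metabolites per class.
  `generate_stoich_objects()` plants the same law directly over hundreds of
  objects for recovery studies.
* `generate_cachexia_experiment()` — five models (MEWO, LNCA, SEKI, CRCA,
  STRV) with three samples per arm; control samples are log-normal around the
  planted abundance (replicate sd 0.05 decades) and experimental samples
  apply a planted per-protein log₂ FC = (slope/1000)·log₁₀(conc mM) +
  N(0, 0.2). The severity gradient plants −100‰ for NIA/B6/PA in the severe
  models (SEKI, CRCA), −30‰ in LNCA, 0 in MEWO and the starvation control.
  Note the planted line is anchored at 1 mM (FC = 1 there); since almost all
  proteins sit below 1 mM, a negative planted slope makes the *less* abundant
  proteins move further from zero — the depression slope, which is
  anchor-invariant, is the planted quantity, while the sign of the group mean
  shift follows from the anchor.
* `generate_ptm_tables()` — 300 shared lysine sites plus 50 extra per table;
  log₂ adjusted FC ~ N(0, 0.3) for aceK/sucK and N(−1, 0.3) for malK by
  default (the planted "V shape"); raw FCs are adjusted FCs times the parent
  protein's FC so the adjustment step recovers them.
* `generate_patient_panel()` — 20/10/27 patients at GPS 0/1/2 (the ordinal
  Glasgow Prognostic Score), six metabolites (betaine, Ser, Thr, choline,
  GAA, Trp) with planted per-GPS-step log₂ declines of 0.4/0.3/0.3/0.5/0.4/
  0.6 and noise sd 0.3; the cachexia label is a logistic draw driven by the
  planted choline + Trp signal.

What the generators do **not** emulate: correlated protein co-regulation,
batch effects, missing-not-at-random censoring, isotope-correction artifacts,
or biological kinetics. Passing the recovery tests therefore shows that the
statistics recover what they claim to estimate under the stated noise model —
not that real data satisfy that model.

# Numerical choices and degenerate inputs

* All OLS fits go through `stats::lm`; identical-value groups in the Welch
  test are special-cased (p = 1) before `t.test` would fail.
* Log fits require ≥3 usable pairs; depression slopes require ≥3 positive
  concentrations and a non-degenerate abundance axis; the dummy regression
  requires ≥10 enzymes, both dummy levels, and refuses perfectly collinear
  predictors by name.
* Zero-variance variables are dropped (with a warning) before PCA rather than
  producing NaN loadings.
* `svm_margin` fits the soft-margin problem; for separable toys with cost
  raised high it matches a hard-margin convex-hull-distance oracle to 1e-6.
  The ±1-side orientation is inferred from the class means of the decision
  values, which is robust for the margin and violation counts reported.
* Permutation p-values use the add-one estimator everywhere. In the
  null-calibration test of the trend statistic, 230 permutations are used so
  the largest attainable p below 0.05 is 11/231 ≈ 0.048 — a grid chosen to
  be conservative at the nominal level rather than exactly on it.
* RNG: every generator and permutation routine takes an explicit seed,
  restores the caller's RNG state on exit, and derives per-trial/per-draw
  seeds from the master seed so single trials can be reproduced.

# Problem sizes used by the checks

The bundled verification runs at desk scale, chosen so the whole suite
completes in well under a minute of compute per module: 500 random toy
catalogs for partition/aggregation exactness; a 2,600-protein catalog for the
1057-protein compartment-matched draws; 500 planted objects for gray-zone
recovery; 200 replicates × 800 proteins for depression-slope CI coverage; 300
shared PTM sites for malonylation-shift recovery; 1,000 null simulations for
trend-test calibration; 50 resampling draws in the acceptance pipeline.
`scripts/acceptance.R` re-runs the full pipeline from a single command-line
seed and writes every headline quantity it computes as JSON.

# Known limitations

* The default formula file is a reconstruction; analyses of real catalogs
  should supply the curated formulas used for the annotation snapshot at
  hand.
* Fold-change estimation assumes arms are exchangeable within a model;
  no batch or sex adjustment is built in (sex is carried in the design table
  for stratified use upstream).
* The SVM margin is a geometric descriptor of a score plot, not a classifier
  performance estimate; no cross-validation is attached by design.
* `rf_mda_select` results depend on the forest implementation's RNG
  consumption; selections are reproducible under a fixed seed but are not
  bitwise invariant to column reordering.
* Dunnett contrasts assume approximate normality of log₂ adjusted FCs within
  acyl groups; the permutation max-*t* route relaxes this at the cost of
  Monte-Carlo error.
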