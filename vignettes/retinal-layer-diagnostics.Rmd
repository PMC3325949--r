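---
title: "Retinal layer morphometry for differentiating parkinsonian syndromes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal layer morphometry for differentiating parkinsonian syndromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkoct)
```

## The scientific problem

Parkinson's disease (PD) and the atypical parkinsonian syndromes —
multiple system atrophy (MSA), progressive supranuclear palsy (PSP) and
corticobasal syndrome (CBS) — are clinically hard to separate, especially
early in the disease course. Spectral-domain optical coherence tomography
(OCT) measures retinal morphology non-invasively, and the retinal layers
turn out to be affected in opposite directions across these syndromes: the
inner nuclear layer (INL) is thickened in PD, while PSP shows a thin outer
nuclear layer (ONL), a thin retinal ganglion cell + inner plexiform layer
complex (RGC+IPL) and a relatively thick outer plexiform layer (OPL).

`parkoct` implements the full analysis chain for per-eye OCT thickness
tables in this setting:

1. a validated two-table cohort container (subjects + eyes) with CSV I/O;
2. quality-control filtering and eye averaging;
3. the measurement conventions for derived features (nasal/temporal layer
   means, the central-ONL rule, between-layer ratios);
4. group statistics (one-way ANOVA with Dunnett many-to-one and Tukey
   all-pairs post-hoc tests, Spearman correlation, a study-style summary
   table);
5. threshold-rule screening with two-by-two metrics and likelihood-ratio
   bands, including the combined PSP rule (ONL/OPL < 3.1 AND INL < 46 µm);
6. an exhaustive search over single-feature and two-feature conjunction
   cutoff rules;
7. a deterministic end-to-end pipeline.

Because no subject-level data are publicly available for this design, the
package ships a synthetic cohort generator whose per-group marginal
distributions are anchored to the published group means and standard
errors. Every downstream stage is therefore testable end-to-end, entirely
in code.

## Measurement conventions

All thicknesses are micrometres, macular volumes cubic millimetres; no
unit conversion happens anywhere. Per eye, the panel
(`panel_fields()`) holds the peripapillar retinal nerve fibre layer
(RNFL; mean + four quadrants from a circular scan), macular thickness and
volume (total, central, peripheral and eight sectors), and the manually
segmented layers measured at their nasal and temporal thickest points
(RGC+IPL, INL, OPL) plus the ONL at its single central thickest point.
Where an ONL presents two maxima instead, `onl_value()` takes the higher
one. Per-layer summaries are the arithmetic mean of the nasal and temporal
points (`layer_mean_nasal_temporal()`).

Two conventions deserve emphasis:

* **Eye handling.** Subject-level analyses use the mean of the two eyes
  (`subject_eye_means()`); a subject with only one usable eye keeps that
  eye's value rather than being dropped, because exclusion is applied per
  analysis only where a needed value is missing. Group statistics can
  alternatively treat each eye as its own (statistically dependent) row
  via `summary_table(..., eye_mode = "duplicates")`; the default is
  `"subject_means"` because duplicate eyes violate the independence
  assumption of one-way ANOVA. Both modes are provided since published
  analyses of this kind have used both, and neither is asserted as the
  canonical computation.
* **Ratios.** `ratio_onl_opl` and `ratio_inl_opl` divide subject-level
  (eye-averaged) layer summaries; the denominator is the *mean* OPL (mean
  of nasal and temporal points). The nasal OPL alone is the more strongly
  affected side in PSP, and a rule on any alternative denominator can be
  expressed directly with `threshold_rule()` on a custom feature column,
  but the mean-OPL convention is the package default.

## Quality control

`qc_filter()` applies two exclusion rules: eyes with scan quality below
20 dB are removed, and subjects whose recorded decimal visual acuity is
below 0.6 (6/10) are removed with all their eyes. Subjects without an
acuity on record are not excluded on acuity (screening cohorts of this
kind typically verify acuity upstream). The filter is idempotent and logs
every exclusion with subject, side and reason.

## The synthetic cohort generator

`default_params()` returns, per group, the published per-field means and
the SDs reconstructed as `SEM × √n` with the subject-level group sizes
(Control 35, PD 40, MSA 19, CBS 10, PSP 15). Subject-level n is used
rather than eye-level n because figure-level reporting in this design is
per subject (mean of the two eyes); this is the conservative choice (a
larger reconstructed SD than the eye-level alternative).

The sampling model in `simulate_cohort()` is, per group with mean vector
µ and SD vector s:

* a subject-level latent panel `L ~ MVN(0, R(ρ_layers))` with
  exchangeable between-layer correlation `ρ_layers` (default 0.3);
* per-eye value `y = µ + s·(√ρ_eyes · L + √(1−ρ_eyes) · E)`, where the eye
  noise `E` is again exchangeable-correlated across layers, so that each
  eye's marginal SD is exactly the target SD, the same-layer between-eye
  correlation is `ρ_eyes` (default 0.8), and the within-eye between-layer
  correlation is `ρ_layers`.

Neither correlation is published for this design, so the defaults are
chosen once as field-plausible values: retinal layer thicknesses of the
two eyes of one person are strongly concordant (test–retest and inter-eye
correlations for OCT thickness measures are typically 0.7–0.9), while
distinct layers share anatomical scaling only weakly. Both are exposed in
`GeneratorParams` for sensitivity analyses. Consequences of this
unidentifiability: marginal group means/SDs — and everything the
acceptance checks target — are exact by construction, but cohort-level
classification performance (a sensitivity/specificity pair on one sampled
cohort of 119) depends on the unobserved joint structure and can only be
bracketed, not reproduced.

Panel values are truncated below (1 µm thickness, 0.01 mm³ volume) by
resampling the whole subject — latent and both eyes — rather than
clipping, which avoids a point mass at the bound; at the default
parameters the truncation probability is negligible. Scan quality is
normal (25 ± 3 dB) truncated at 20 dB so that default cohorts pass QC
untouched. Clinical covariates (age, disease duration, follow-up, Hoehn &
Yahr, UPDRS-III on/off) are drawn from the published clinical means/SEMs,
clamped to their valid ranges, and deliberately carry **no** correlation
with the layer panel: the study setting reports no correlation of disease
duration or UPDRS-III with any retinal layer. Controls get an age-matched
age distribution (64 ± 9 y; no control covariate table exists) and no
disease covariates. Sex is balanced Bernoulli.

What the generator does *not* emulate: measurement error as an image
process (speckle, segmentation jitter beyond the marginal SD),
non-normal or skewed layer distributions, the bimodal sub-structure
reported for CBS (its INL/OPL ratio clusters in two subgroups in the real
cohort — the generator draws one normal component), longitudinal change,
and any layer–covariate coupling. Passing tests therefore demonstrate
correctness of the *machinery* under the published marginal conditions,
not clinical performance on real patients.

**Determinism.** A single integer seed governs all draws via one
`set.seed()` at entry and a fixed draw order (groups in parameter order;
within a group: latent panel, left-eye noise, right-eye noise, clinical
covariates, sex, quality). Identical parameters and seed reproduce a
byte-identical cohort.

## Group statistics

`anova_oneway()`, `dunnett_vs_control()` and `tukey_all_pairs()` wrap the
classical fixed-effects machinery. Dunnett adjusted p-values use the
multivariate-t distribution with the exact correlation structure implied
by the observed, generally unbalanced, group sizes (via `multcomp`;
deterministic numerical integration rather than Monte Carlo, accurate well
below 0.001 on the critical point). The test suite cross-checks this
against an independent Monte-Carlo multivariate-t simulation and verifies
the k = 1 reduction to the pooled t-test and the family-wise error rate
under a five-group null. Tukey uses the studentized-range distribution.
No multiplicity correction is applied *across* the ~40 panel parameters —
the summary table reports per-parameter families only, matching standard
practice for this kind of exploratory morphometry table.

`spearman_cor()` uses average ranks for ties and switches the p-value
method at n = 9: exact permutation below (available without ties),
large-sample approximation otherwise.

Degenerate inputs are handled explicitly: zero total variance is an error
for the ANOVA; zero within-group variance everywhere makes the summary
table report means with `NA` significance flags and a warning rather than
fabricating p-values.

## Diagnostic rules and screening metrics

`psp_rule()` returns the conjunction *ONL/OPL ratio < 3.1 AND mean INL <
46 µm*, strict at both boundaries. The "below" direction is forced by the
group-level anatomy (PSP has the lowest ONL and the highest OPL of the
five groups, hence the lowest ratio, and a thin INL while PD's INL is
thickened). `rule_confusion()` counts subjects — the classification unit
is the eye-averaged subject, consistent with subject-level reporting —
and excludes (with a log) subjects missing a needed feature.
`diagnostic_metrics()` computes sensitivity, specificity,
LR+ = sens/(1−spec) and LR− = (1−sens)/spec, keeping raw values alongside
display roundings (half away from zero: 2 decimals for LRs, whole percent
for proportions). Specificity 1 yields a flagged infinite LR+;
specificity 0 a flagged undefined LR−; neither is silently propagated.

The qualitative bands: LR+ ≥ 50 excellent, 10–50 good, 2–10 fair; LR−
< 0.05 excellent, 0.05–0.1 good, 0.1–0.3 fair. The verbal band
definitions leave edge inclusivity open; the package fixes half-open
`[lower, upper)` intervals for LR+ and `<0.05`, `[0.05, 0.1)`,
`[0.1, 0.3]` for LR− as its documented convention.

## The cutoff search

`search_rules()` enumerates, for every feature in the search space (base
features plus requested pairwise ratios), every decision-distinct cutoff —
midpoints between consecutive distinct sorted values
(`candidate_cutoffs()`) — in both directions, and every conjunction of two
such thresholds on distinct features. Conjunctions are capped at two
components to keep the space interpretable and bounded; this mirrors the
combined two-layer test the search is built to contextualize. The default
ranking criterion is Youden's J = sensitivity + specificity − 1; a
lexicographic sensitivity-then-specificity alternative is provided because
a rule-out screen for a rare syndrome privileges sensitivity. Ties break
deterministically (fewer components, feature names, smaller cutoffs), so
the ranking is total and reproducible. `evaluate_rule_in_search()` ranks a
named rule (by insertion if it lies outside the grid) — this is how the
claim "no other searched combination does better" is made checkable.

All search output is in-sample (resubstitution) and labelled as such: with
~10⁵ candidate rules on ~120 subjects, the top of the ranking is
optimistically biased by selection, and no cross-validation or bootstrap
optimism correction is attempted (deliberately out of scope; the search
substantiates a relative claim on the same data, not a generalization
claim).

## The pipeline

`run_pipeline(run_config(...))` composes simulate/read → QC → features →
group summary → screening → search, writes
`subjects.csv`/`eyes.csv`/`features.csv`/`summary.csv`/`comparisons.csv`/
`metrics.json`/`ranked_rules.csv`/`run.log` into the output directory, and
is hash-reproducible under a fixed seed. `pipeline_report()` renders a
markdown summary from the in-memory bundle or the on-disk directory.

```{r pipeline, eval = FALSE}
bundle <- run_pipeline(run_config(seed = 1, out_dir = "run1"))
writeLines(pipeline_report(bundle))
```

## Numerical and design choices, in brief

* SD reconstruction uses subject-level n (conservative; figure-level unit).
* Truncation by whole-subject resampling, never clipping.
* Clinical covariates clamped (not resampled) to valid ranges: a point
  mass at a clinical scale's end is acceptable where a thickness point
  mass is not, and some published clinical SEMs are large enough relative
  to their means that resampling would visibly distort the mean.
* Display rounding is half-away-from-zero; raw values are always kept
  because printed two-decimal LRs are not exactly recomputable from
  rounded sensitivity/specificity pairs.
* Significance flags are exactly `adjusted p < α` with α = 0.05 by
  default, exposed in every comparison function.
* Test problem sizes are chosen for tight-but-fast Monte Carlo: marginal
  recovery at 2 × 10⁴ subjects per group (4-SE tolerance) in module tests
  and 10⁵ per group in the acceptance suite; family-wise error at 2000
  null replicates; the acceptance script aggregates 10⁶ subjects per
  target in ten equal chunks of 10⁵ (equal weights make the chunked mean
  exact) to bound peak memory.

## Known limitations

* Correlation structure (between layers, between eyes) is assumed
  exchangeable and is not identifiable from published summaries; cohort-
  level sensitivity/specificity of the PSP rule on simulated 119-subject
  cohorts varies with those assumptions and with sampling noise.
* The generator is Gaussian; real layer thickness distributions may be
  skewed, and the CBS group's reported bimodality is not reproduced.
* All screening metrics are resubstitution estimates; no out-of-sample
  performance is claimed anywhere.
* The package starts from segmented thickness tables; OCT image parsing
  and segmentation are upstream and out of scope.
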