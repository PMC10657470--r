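---
title: "Methods: microbiome-to-APNS modeling in gutapns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbiome-to-APNS modeling in gutapns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, the defaults and the design decisions
behind `gutapns`, in the spirit of a statistical supplement. Everything
quantitative stated here is computed by the package's test suite or by
`scripts/acceptance.R`; nothing is asserted beyond what those runs check.

## Study design and assumptions

The pipeline targets a longitudinal emergency-department trauma cohort:
each subject provides **one** stool sample (shotgun-profiled into species
relative abundances and stratified pathway abundances) and repeated APNS
assessments at weeks 2, 8 and 12 post-trauma. Two assumptions follow:

* **Microbiome stability.** The single sample stands in for the subject's
  microbiome at all three assessment weeks. All feature matrices therefore
  contain rows that are *identical within subject* — a fact with strong
  consequences for the mixed-effect random forest (below).
* **Subject-level exchangeability.** Between-subject heterogeneity not
  captured by covariates or taxa is modeled as a Gaussian random intercept.

## Outcome instruments

PCL-5: 20 items scored 0–4, summed to 0–80. The diagnostic grouping is
*raw score > 31* versus *≤ 31*; the text of instrument guidelines often
says "a sum of 31", but the operational grouping places 31 itself in the
negative class, and the cut is exposed as a parameter (`ptsd_cut`).
PROMIS Depression 8b is carried as a t-score (population mean 50, SD 10);
depression is *t ≥ 60*, one SD above the mean. Somatic symptoms are a
count of 12 yes/no Rivermead items, hence an integer in 0–12 and modeled
generatively as Binomial(12, ·).

## The synthetic cohort generator

`sim_config()` defaults define the study conditions used throughout the
tests and the acceptance script:

| parameter | default | rationale |
|---|---|---|
| `n_subjects` | 51 | analyzed cohort size |
| `n_species` | 200 | typical species count after profiling |
| `timepoints` | 2, 8, 12 weeks | assessment schedule |
| `sigma_b`, `sigma_e` | 2, 1 (latent scale) | strong subject heterogeneity (ICC 0.8) |
| `sparsity` | 0.25 | fraction of species zeroed per sample |
| `species_log_sd`, `sample_log_sd` | 2, 1 | overdispersed log-normal intensities |
| `effect_sizes` | 12, 6, 3, 1.5, 0.75 | see below |
| `time_slope` | −0.05 / week | mild symptom decline |

Abundances are log-normal intensities, zeroed below the per-sample 25%
quantile (a detection limit) and closed to 100%. The five *effector*
species are the most abundant ones — high-prevalence taxa whose
arcsine-square-root transformed abundance has spread ≈ 0.13 across
subjects. The planted coefficients decay geometrically from 12 so that the
dominant effector contributes about 1.5 residual SDs of signal (12 × 0.13
≈ 1.6) and exactly one feature dominates; these values were chosen for
testability of recovery, not as empirical effect sizes, since usable
microbiome-to-APNS effect sizes are not available. Latent responses map to
instruments affinely (PCL-5: 30 + 5z rounded and clipped; PROMIS: 50 + 3z)
or through a logistic Binomial (somatic). Each public generator stage
derives its RNG stream from the single config seed plus a fixed stage
offset, so stages are reproducible both standalone and within
`simulate_study()`.

What the generator does **not** emulate: phylogenetic correlation between
species, strain-level structure, longitudinal microbiome drift,
covariate–microbiome confounding, and non-Gaussian outcome noise beyond
the instrument maps. Passing recovery tests on this generator therefore
demonstrates internal consistency of the estimators under the stated
model, not performance on real cohorts.

Stratified pathway tables assign each configured pathway a set of
contributing species with fixed weights; the community total is the sum of
the strata, so generated tables satisfy the format invariants by
construction. The default pathway set is the five arginine-, ornithine-
and citrulline-biosynthesis pathways the contribution analysis focuses on.

## Per-species screen and variance partition

Each species is tested in its own REML mixed model: outcome ~ covariates
(age, sex, BMI, race/ethnicity), days since trauma, categorical week,
arcsine-square-root abundance (proportions, i.e. percent/100), with a
subject random intercept. The abundance term's Wald p-value (normal
reference) is Benjamini–Hochberg adjusted across species — BH being the
field default where only "FDR corrected" is specified — and selection is
q ≤ 0.05. Species with constant transformed abundance or failed fits are
assigned p = 1 and flagged rather than dropped, keeping the BH family size
stable. lme4's boundary (singular) fits with `sigma_b = 0` estimates are
*not* treated as failures: they are legitimate and are exactly what makes
the screen agree with ordinary least squares when the data carry no
subject heterogeneity (a property the suite checks).

Selected species are combined into one global mixed model (aliased
features dropped by a QR rank check, with a warning; zero selected
features returns an explicit "no model" object). The variance partition is
sequential (Type I) ANOVA with covariates entered before species terms:
sequential sums of squares add up by construction, which a pie-style share
requires, and covariates-first is conservative toward the microbiome. Each
term's share is `SS / (Σ fixed SS + residual SS)`; including the residual
makes "the microbiome accounts for X%" interpretable as a share of total
outcome variation. Fixed-effects-only ratios are reported alongside
(`ratio_fixed`), since either convention is defensible. The microbiome
share of a run with no selected species is 0 by definition.

## Mixed-effect random forest

The model is `y = f(X) + b_subject + ε` with a regression forest for `f`
(ranger: 300 trees, `mtry = ⌈p/3⌉`, minimum leaf 3 — standard regression
defaults) and BLUP intercepts
`b_i = σ²_b · Σ r_i / (σ²_e + n_i σ²_b)`. The classical fitting recipe
alternates: fit the forest on the working response `y − b`, re-estimate
`b` and the variance components from the residuals by the EM updates, and
monitor a generalized log-likelihood. Three findings from this design —
all reproducible from the package — shaped the implementation:

1. **In-sample residuals collapse `σ²_b`.** With one sample per subject,
   a subject's rows have identical features and bootstrap memorization
   lets trees reproduce most of each cluster's offset in-sample;
   residual-based variance updates then report `σ²_b ≈ 0` even when the
   true intercept variance dominates. The reported variance components
   are therefore re-estimated *honestly*: residuals are taken against
   **cluster-level out-of-bag** predictions (averaging only trees whose
   bootstrap contains no row of that subject — row-level OOB is
   insufficient precisely because of the duplicated features), and the
   random-intercept EM runs to convergence on those residuals with the
   forest fixed. This is the same logic as estimating a forest's error
   variance from OOB rather than training residuals.

2. **Alternation is self-defeating for cluster-constant features.**
   Subtracting the BLUP from the working response removes between-subject
   variation — which is *all* the variation a cluster-constant feature
   has. Each additional alternation pass transfers a further fraction of
   the generalizable feature signal into the intercepts (the forest's
   fixed part visibly flattens pass by pass), with no identifiable
   optimum: `f(X_i)` and `b_i` are confounded beyond what cross-subject
   generalization can separate. The default is therefore a **single
   pass** (`max_iter = 1`): one forest fit on the raw response plus the
   honest variance/intercept estimation. For designs whose features vary
   within subject the alternation behaves conventionally and `max_iter`
   can be raised; the loop, the EM updates and the GLL trace are all
   retained for that case.

3. **Prediction intercepts must complement the forest actually used.**
   Predictions use the full forest, which for a *seen* subject already
   reproduces part of that subject's offset. Adding the honest-residual
   BLUP on top would double-count cluster effects (measurably inflating
   held-out residuals and even reversing permutation-importance signs).
   `b_hat` is therefore the BLUP of the **in-sample** residuals evaluated
   at the **honest** variance components: it adds only what the forest
   does not already reproduce. Correlation with the true intercepts is
   unaffected (correlation is scale-invariant), which is how the
   intercept-recovery check is posed.

The GLL, `Σ‖y−f−b‖²/σ²_e + Σb²/σ²_b + N log σ²_e + q log σ²_b` (b-terms
omitted in the `σ²_b = 0` limit), is exposed both as a closed-form
function and as a model evaluation, and the trace is stored per iteration.

## Evaluation and permutation importance

The longitudinal split trains on weeks 2 and 8 and tests on week 12 —
forecasting the late outcome from early outcomes and the stable
microbiome. The pipeline runs over ten seeds (defaults 0–9); per seed it
records test RMSE and Pearson correlation, and permutation importance on
the held-out rows: the mean increase in test MSE over 5 permutations of
one feature column, with random intercepts held fixed, computed in one
batched forest call. Constant columns get importance 0 by convention.
Aggregation averages importance over seeds (features missing from failed
seeds are averaged over the seeds that scored them), ranks descending with
lexicographic tie-break, reports only features with positive mean
importance up to the top 15, and attaches a direction as the Spearman
correlation between feature value and outcome across all subject-week
rows.

A caveat the suite documents: under feature subsampling (`mtry < p`),
duplicating a feature column can *inflate* both copies' permutation
importance rather than split it — duplication doubles the chance the
signal is available at any split. The classical "importance splits across
correlated copies" intuition holds under bagging (`mtry = p`), and that is
the regime in which the package tests it.

## Pathway contributions

For one pathway, each sample's stratified rows are pooled to the requested
rank (genus or species; several strata of one taxon sum) and normalized to
fractions; samples with zero stratified total become `NA` and are excluded
from group summaries. Group tables average per-sample fractions
(mean-of-fractions, the default, so high-biomass samples do not dominate)
or pool abundances first (`mode = "pooled"`), then renormalize to 100 and
round to 2 decimals. Groups are defined by the week-12 diagnosis by
default — the headline outcome week — and the grouping week is a
parameter. Species-rank output refines genus-rank output exactly (a tested
identity), because both normalize by the same per-sample stratified total.

## Power

The `fisher_z` mode applies the Pearson-correlation power approximation to
the Spearman coefficient, matching standard power software; at ρ = 0.5,
n = 51, α = 0.05 (two-sided, α and sidedness being the package defaults
where unstated) it yields 0.97 to two decimals. The `simulation` mode is
the ground truth: it draws bivariate normal samples with Pearson
correlation `2·sin(πρ/6)` — so the *population Spearman* correlation
equals ρ — and reports the rejection rate of the two-sided Spearman test.
With 10,000 draws the two modes agree within 0.02 at the design point.
`minimum_n` inverts the Fisher-z power by bracketing and bisection and
enforces the strict post-condition `power(n) ≥ target > power(n−1)`; note
that because power at n = 51 is 0.9675 (< 0.97 though it prints as 0.97),
the smallest n whose power *reaches* 0.97 is 52.

## Numerical choices and degenerate inputs

* `arcsine_sqrt` clamps inputs within 1e-12 of [0, 1]; further out is a
  domain error.
* Per-sample abundance sums may exceed 100 by at most 1e-6; stratified
  pathway sums may exceed the community total by 1e-6 absolute plus 1e-6
  relative (float round-trip headroom).
* `retention_percent` rounds half-up to one decimal (69.8% = 74/106,
  93.2% = 69/74).
* Internal `σ²_b` estimates below 1e-10 snap to exactly 0, activating the
  documented no-intercept GLL limit.
* Zero selected features, empty diagnosis groups, all-zero pathway
  samples, unseen prediction clusters and single-seed aggregation all
  return explicit degenerate results rather than errors; single-cluster
  MERF designs and non-finite responses are errors.

## Problem sizes

The test suite and acceptance script run at the study's design size (51
subjects, 200 species, 153 observations) for single fits and ten-seed
evaluations; replicated calibration checks use 20 replicates in the suite
and 10 in the acceptance script; the power simulation uses 10,000 draws
(2,000 in the quick in-suite check). These sizes make the full suite and
the script each complete in minutes on one CPU while keeping Monte Carlo
error well inside the asserted tolerances.

## Known limitations

* The honest variance estimate inherits cluster-OOB prediction noise and
  tends to overshoot `σ²_b` modestly (the recovery check asserts a factor
  of two, not unbiasedness).
* With cluster-constant features, `f` and `b` are separated only through
  cross-subject generalization; subjects whose microbiome poorly predicts
  their outcome level are absorbed into `b_hat` regardless of cause.
* Permutation importance shares the usual correlated-feature caveats;
  compositional closure correlates all taxa mechanically.
* The somatic-count outcome (Binomial, weak logistic link) carries the
  least signal per observation of the three instruments; diffuse,
  low-magnitude importance tables for it are expected behavior, not a
  defect.
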