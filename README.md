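# gutapns

Analysis pipeline linking gut microbiome taxonomic and functional profiles to
adverse post-traumatic neuropsychiatric sequelae (APNS) — PTSD, depression and
somatic symptoms — in a longitudinal emergency-department trauma cohort.

The package is written for microbiome researchers who have shotgun-metagenomic
profiles (MetaPhlAn-style species tables, HUMAnN-style stratified pathway
tables) and repeated APNS assessments at roughly 2, 8 and 12 weeks
post-trauma, with a single stool sample per subject collected under the
assumption that the adult gut microbiome is stable over this window.

## What it computes

**Outcome scoring.** PCL-5 raw score (sum of 20 items, 0–80; PTSD when the
score exceeds 31), PROMIS Depression 8b t-score (mean 50, SD 10; depression
when t ≥ 60) and a 12-item Rivermead somatic symptom count.

**Variance screening (linear mixed models).** For each species *s* the model

```
y_it = β₀ + covariatesᵀβ + γ_s · asin√(p_is) + slope·week_t + b_i + ε_it,
b_i ~ N(0, σ²_b),  ε_it ~ N(0, σ²_e)
```

is fit by REML (lme4) with subject random intercept; the Wald p-value of the
abundance term is Benjamini–Hochberg adjusted across species and features
with q ≤ 0.05 are combined into a global mixed model. Sequential (Type I)
ANOVA expresses each term's sum of squares as a share of the total (fixed +
residual), giving the "microbiome share" of outcome variance.

**Mixed-effect random forest (MERF).** A regression forest for the fixed part
plus BLUP-estimated per-subject random intercepts:
`y = f(X) + b_subject + ε`. The week-2/8 observations train the model and
the unseen week-12 observations test it (RMSE, Pearson correlation of true
vs predicted); the pipeline is repeated over ten seeds and features are
ranked by permutation importance on the held-out rows, with direction given
by Spearman correlation. Variance components are estimated honestly from
cluster-level out-of-bag residuals (see the methods vignette for why this
matters when each subject contributes a single microbiome sample).

**Pathway contributions.** Per-taxon percent contribution to
arginine/ornithine/citrulline biosynthesis pathways from stratified
`pathway|taxon` rows, averaged within diagnosis groups (e.g. PTSD raw score
≤ 31 vs > 31) and renormalized to 100%.

**Power.** Power of a one-sample Spearman correlation test via the Fisher-z
approximation (`power = Φ(√(n−3)·atanh ρ − z_{1−α/2}) + Φ(−√(n−3)·atanh ρ −
z_{1−α/2})`), with a Monte Carlo simulation mode as ground truth.

Because the study's sequence data are not shipped, the package includes a
first-class synthetic-cohort generator (`simulate_study()`) that reproduces
the design: 51 subjects, compositional species profiles with 25% zeros,
planted effector species, subject random intercepts (σ_b = 2, σ_e = 1 on the
latent scale) and consistent stratified pathway tables.

## Worked example

```r
library(gutapns)

study <- simulate_study(sim_config(seed = 0))

# screen species for the depression outcome
scr <- screen_features(study$panel, study$species, study$cohort, "promis_t")
sum(scr$selected)
#> [1] 1
gl <- fit_global_lmm(scr, study$panel, study$species, study$cohort)
microbiome_share(variance_partition(gl))
#> [1] 0.332

# MERF evaluation over ten seeds
feats <- merf_features(study$species, study$cohort)
runs <- run_seeds(study$panel, feats, "promis_t", seeds = 0:9)
imp <- aggregate_importance(runs, feature_data = feats[study$panel$subject_id, ],
                            outcome_values = study$panel$promis_t)
head(imp, 2)[, c("feature", "mean_importance", "direction_rho")]
#>           feature mean_importance direction_rho
#> 1 s__Genus13_sp01      14.7078282     0.6573939
#> 2 s__Genus34_sp02       0.0496679    -0.2129060

# the study's power calculation
spearman_power(rho = 0.5, n = 51, alpha = 0.05)
#> [1] 0.9675351
```

The selected species and the top-ranked feature are the same planted
dominant effector (`s__Genus13_sp01`, truth coefficient 12): the screen
finds it, the global model attributes 33% of outcome variance to the
microbiome terms, and the forest ranks it first in all ten seeds with a
positive direction. The power value rounds to 0.97 at the study's design
size of 51 subjects.

The numbered scripts under `analysis/` run the same stages end to end
(`01_simulate.R` … `05_power.R`), writing all tables under `results/`; the
`run_all(run_config())` function is the programmatic equivalent.

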