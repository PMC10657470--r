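# Synthetic cohort generator. Emulates the statistical structure the
# downstream analyses assume: compositional, sparse, overdispersed species
# profiles (one stool sample per subject, reused across timepoints under
# the microbiome-stability assumption), subject-level random intercepts,
# planted species effects on the three APNS outcomes, and stratified
# pathway tables consistent with the species table.

#' Simulation configuration
#'
#' Defaults describe the study design the pipeline targets: 51 subjects,
#' 200 species, outcomes at weeks 2/8/12, random-intercept SD
#' `sigma_b = 2` and residual SD `sigma_e = 1` on the latent outcome
#' scale, and five planted effector species whose coefficients decay
#' geometrically so that exactly one feature dominates.
#'
#' @param n_subjects number of subjects (one stool sample each).
#' @param n_species number of species in the profile.
#' @param species_per_genus species assigned per synthetic genus.
#' @param n_effectors number of species with planted outcome effects; the
#'   effectors are the `n_effectors` most abundant species.
#' @param effect_sizes coefficients per arcsine-square-root abundance unit,
#'   length `n_effectors`. The default top coefficient (12) yields roughly
#'   1.5 residual SDs of planted signal given the ~0.13 spread of the
#'   transformed abundance of a dominant species.
#' @param covariate_effects named vector: latent effects of standardized
#'   age, female sex and standardized BMI.
#' @param time_slope latent change per week post-trauma.
#' @param sigma_b,sigma_e SD of the subject random intercept and of the
#'   residual, latent scale.
#' @param timepoints assessment weeks.
#' @param species_log_mean,species_log_sd between-species spread of
#'   log-intensities (log-normal base abundances).
#' @param sample_log_sd within-species, between-sample log-normal noise.
#' @param sparsity fraction of species zeroed per sample (detection limit),
#'   applied before closure to 100%.
#' @param pcl5_center,pcl5_scale affine map from the latent response to the
#'   PCL-5 raw score (then rounded and clipped to 0--80).
#' @param promis_center,promis_scale affine map to the PROMIS t-score
#'   scale (mean 50, SD 10 population scale).
#' @param somatic_intercept,somatic_slope logistic map from the latent
#'   response to the per-symptom probability of a Binomial(12) count.
#' @param pathway_spec optional list of pathway specifications (see
#'   [simulate_pathways()]); `NULL` uses the built-in arginine-pathway set.
#' @param seed integer seed; all stages derive their RNG state from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 51, n_species = 200,
                       species_per_genus = 5, n_effectors = 5,
                       effect_sizes = c(12, 6, 3, 1.5, 0.75),
                       covariate_effects = c(age = 0.2, sex_female = -0.3, bmi = 0.25),
                       time_slope = -0.05,
                       sigma_b = 2, sigma_e = 1,
                       timepoints = c(2, 8, 12),
                       species_log_mean = 0, species_log_sd = 2,
                       sample_log_sd = 1, sparsity = 0.25,
                       pcl5_center = 30, pcl5_scale = 5,
                       promis_center = 50, promis_scale = 3,
                       somatic_intercept = -0.3, somatic_slope = 0.3,
                       pathway_spec = NULL, seed = 0) {
  cfg <- as.list(environment())
  if (sigma_b < 0 || sigma_e < 0)
    stop("config error: sigma_b and sigma_e must be >= 0")
  if (n_effectors > n_species)
    stop("config error: n_effectors exceeds n_species")
  if (length(effect_sizes) != n_effectors)
    stop("config error: effect_sizes must have length n_effectors")
  if (sparsity < 0 || sparsity >= 1)
    stop("config error: sparsity must lie in [0, 1)")
  if (n_subjects < 2 || n_species < 1)
    stop("config error: need at least 2 subjects and 1 species")
  structure(cfg, class = "sim_config")
}

# Deterministic synthetic taxonomy: species_per_genus consecutive species
# share a genus; full seven-rank lineage strings so genus parsing works.
synthetic_lineage <- function(n_species, species_per_genus) {
  g <- (seq_len(n_species) - 1) %/% species_per_genus + 1
  sp <- (seq_len(n_species) - 1) %% species_per_genus + 1
  sprintf(paste0("k__Bacteria|p__Phylum%02d|c__Class%02d|o__Order%02d|",
                 "f__Family%02d|g__Genus%02d|s__Genus%02d_sp%02d"),
          (g - 1) %% 6 + 1, (g - 1) %% 12 + 1, g, g, g, g, sp)
}

#' Simulate a compositional species abundance table
#'
#' Per subject, species intensities are drawn log-normally around
#' species-specific base levels, the lowest `sparsity` fraction is set to
#' zero (detection limit), and the remainder is closed to sum to 100.
#'
#' @param config a [sim_config()].
#' @return A [species_table()] with one sample per subject (`S001`, ...).
#' @export
simulate_abundances <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_subjects; p <- config$n_species
  base <- stats::rnorm(p, config$species_log_mean, config$species_log_sd)
  inten <- exp(outer(rep(1, n), base) +
               matrix(stats::rnorm(n * p, 0, config$sample_log_sd), n, p))
  k <- floor(config$sparsity * p)
  if (k > 0) {
    for (i in seq_len(n)) {
      inten[i, order(inten[i, ])[seq_len(k)]] <- 0  # exactly k zeros per sample
    }
  }
  vals <- t(inten / rowSums(inten) * 100)
  species_table(vals,
                species = synthetic_lineage(p, config$species_per_genus),
                samples = sprintf("S%03d", seq_len(n)))
}

#' Simulate subject metadata
#'
#' Draws age, sex, BMI, race/ethnicity and days-since-trauma with marginal
#' distributions matching a middle-aged, majority-White/Black trauma
#' cohort whose stool samples arrive a median of ~45 days post-trauma.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `subject_id`, `sample_id`, `age`,
#'   `sex`, `bmi`, `race_ethnicity`, `days_since_trauma`.
#' @export
simulate_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- config$n_subjects
  data.frame(
    subject_id = sprintf("P%03d", seq_len(n)),
    sample_id = sprintf("S%03d", seq_len(n)),
    age = pmin(90, pmax(18, round(stats::rnorm(n, 52, 15)))),
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.51, 0.49)),
    bmi = pmin(55, pmax(16, round(stats::rnorm(n, 29, 6), 1))),
    race_ethnicity = sample(c("White", "Black", "Asian", "Other"), n,
                            replace = TRUE, prob = c(0.61, 0.25, 0.02, 0.12)),
    days_since_trauma = pmin(182L, pmax(5L, as.integer(round(
      stats::rlnorm(n, log(45), 0.8))))),
    stringsAsFactors = FALSE)
}

# Effectors are the most abundant species: high-prevalence features whose
# transformed abundance has enough spread to carry a detectable signal.
planted_effectors <- function(species, n_effectors) {
  species$species[order(rowMeans(species$values),
                        decreasing = TRUE)[seq_len(n_effectors)]]
}

standardize_covariates <- function(cohort) {
  cbind(age = (cohort$age - 50) / 15,
        sex_female = as.numeric(cohort$sex == "female"),
        bmi = (cohort$bmi - 29) / 6)
}

#' Simulate longitudinal APNS outcomes with planted species effects
#'
#' Generates, per outcome, a latent response
#' `z_it = sum_s gamma_s * asin(sqrt(p_is)) + covariates' beta +
#' time_slope * week + b_i + e_it` with `b_i ~ N(0, sigma_b^2)`,
#' `e_it ~ N(0, sigma_e^2)`, then maps it to the instrument scales:
#' PCL-5 raw score (affine, rounded, clipped to 0--80), PROMIS t-score
#' (affine), somatic count (`Binomial(12, logistic(z))`).
#'
#' @param config a [sim_config()].
#' @param species a [species_table()] aligned with `cohort$sample_id`.
#' @param cohort metadata from [simulate_metadata()].
#' @return list with `panel` (long data.frame: `subject_id`, `week`,
#'   `pcl5_raw`, `promis_t`, `somatic_count`) and `truth` (planted
#'   effectors and coefficients, per-subject random intercepts, latent
#'   responses and their fixed parts, and outcome-scale SDs).
#' @export
simulate_outcomes <- function(config, species, cohort) {
  stopifnot(inherits(config, "sim_config"), inherits(species, "species_table"))
  if (!setequal(cohort$sample_id, species$samples) ||
      nrow(cohort) != length(species$samples))
    stop("alignment error: cohort sample_ids do not match species table samples")
  set.seed(config$seed + 3L)
  n <- nrow(cohort)
  prop <- t(species$values[, cohort$sample_id, drop = FALSE]) / 100
  eff <- planted_effectors(species, config$n_effectors)
  A <- asin(sqrt(prop[, eff, drop = FALSE]))
  fixed_micro <- as.numeric(A %*% config$effect_sizes)
  Z <- standardize_covariates(cohort)
  ce <- config$covariate_effects
  fixed_cov <- as.numeric(Z %*% ce[colnames(Z)])

  weeks <- config$timepoints
  idx <- rep(seq_len(n), times = length(weeks))
  wk <- rep(weeks, each = n)
  fixed <- fixed_micro[idx] + fixed_cov[idx] + config$time_slope * wk

  outcomes <- c("pcl5", "promis", "somatic")
  b <- matrix(stats::rnorm(n * 3, 0, config$sigma_b), n, 3,
              dimnames = list(cohort$subject_id, outcomes))
  latent <- data.frame(subject_id = cohort$subject_id[idx], week = wk,
                       fixed = fixed)
  for (o in outcomes) {
    e <- stats::rnorm(length(idx), 0, config$sigma_e)
    latent[[paste0("z_", o)]] <- fixed + b[idx, o] + e
  }
  panel <- data.frame(
    subject_id = latent$subject_id, week = latent$week,
    pcl5_raw = as.integer(pmin(80, pmax(0, round(
      config$pcl5_center + config$pcl5_scale * latent$z_pcl5)))),
    promis_t = config$promis_center + config$promis_scale * latent$z_promis,
    somatic_count = stats::rbinom(length(idx), 12, stats::plogis(
      config$somatic_intercept + config$somatic_slope * latent$z_somatic)),
    stringsAsFactors = FALSE)

  truth <- list(
    effectors = eff,
    effect_sizes = stats::setNames(config$effect_sizes, eff),
    b = b, sigma_b = config$sigma_b, sigma_e = config$sigma_e,
    outcome_sigma_b = c(pcl5 = config$pcl5_scale * config$sigma_b,
                        promis = config$promis_scale * config$sigma_b,
                        somatic = NA_real_),
    latent = latent)
  list(panel = panel, truth = truth)
}

default_pathway_spec <- function(species) {
  pw <- c("ARG-POLYAMINE-SYN: superpathway of arginine and polyamine biosynthesis",
          "ARGSYNBSUB-PWY: L-arginine biosynthesis II (acetyl cycle)",
          "ARGININE-SYN4-PWY: L-ornithine de novo biosynthesis",
          "ARGSYN-PWY: L-arginine biosynthesis I (via L-ornithine)",
          "CITRULBIO-PWY: L-citrulline biosynthesis")
  top <- species$species[order(rowMeans(species$values), decreasing = TRUE)]
  lapply(seq_along(pw), function(k) {
    contrib <- top[((k - 1) * 4 + 1):((k - 1) * 4 + 4)]
    list(pathway = pw[k], species = contrib, weights = c(2, 1, 0.5, 0.25))
  })
}

# "g__Genus01.s__Genus01_sp02" from a full lineage string
strat_taxon <- function(lineage) {
  g <- sub(".*(g__[^|]+).*", "\\1", lineage)
  s <- sub(".*(s__[^|]+).*", "\\1", lineage)
  paste0(g, ".", s)
}

#' Simulate a stratified pathway abundance table from a species table
#'
#' Each configured pathway receives one stratified row per contributing
#' species, with abundance `weight * species abundance`; the community
#' total is the sum of the strata, so the generated table satisfies the
#' pathway-table invariants by construction. An `UNMAPPED` row is added
#' for format realism.
#'
#' @param config a [sim_config()]; `config$pathway_spec` may be a list of
#'   `list(pathway=, species=, weights=)` entries (default: an
#'   arginine/ornithine/citrulline pathway set over the most abundant
#'   species).
#' @param species a [species_table()].
#' @return A [pathway_table()].
#' @export
simulate_pathways <- function(config, species) {
  stopifnot(inherits(config, "sim_config"), inherits(species, "species_table"))
  spec <- config$pathway_spec
  if (is.null(spec)) spec <- default_pathway_spec(species)
  keys <- character(0); rows <- list()
  for (pw in spec) {
    if (!all(pw$species %in% species$species))
      stop("config error: pathway spec names unknown species")
    strat <- species$values[pw$species, , drop = FALSE] * pw$weights
    total <- colSums(strat)
    keys <- c(keys, pw$pathway,
              paste0(pw$pathway, "|", strat_taxon(pw$species)))
    rows <- c(rows, list(total), lapply(seq_len(nrow(strat)),
                                        function(i) strat[i, ]))
  }
  keys <- c(keys, "UNMAPPED")
  rows <- c(rows, list(rep(1000, length(species$samples))))
  pathway_table(do.call(rbind, rows), row_keys = keys,
                samples = species$samples)
}

#' Simulate a complete synthetic study
#'
#' Runs the abundance, metadata, outcome and pathway generators under one
#' configuration seed and bundles the results.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_study` with elements `species`,
#'   `pathways`, `cohort`, `panel`, `truth`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  species <- simulate_abundances(config)
  cohort <- simulate_metadata(config)
  out <- simulate_outcomes(config, species, cohort)
  pathways <- simulate_pathways(config, species)
  structure(list(species = species, pathways = pathways, cohort = cohort,
                 panel = out$panel, truth = out$truth, config = config),
            class = "synthetic_study")
}
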