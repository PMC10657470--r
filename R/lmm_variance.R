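# Two-tier linear mixed-model analysis: per-species screening of
# arcsine-square-root transformed abundances with BH false-discovery
# control, a global mixed model over the selected species, and a
# sequential sum-of-squares partition of outcome variance.

#' Arcsine square root transform
#'
#' Variance-stabilizing transform `asin(sqrt(p))` for proportions.
#'
#' @param p numeric vector of proportions in `[0, 1]`; values within
#'   `1e-12` outside the interval are clamped, anything further is a
#'   domain error.
#' @return transformed values in `[0, pi/2]`.
#' @export
arcsine_sqrt <- function(p) {
  if (any(!is.finite(p)) || any(p < -1e-12) || any(p > 1 + 1e-12))
    stop("domain error: proportions must lie in [0, 1]")
  asin(sqrt(pmin(1, pmax(0, p))))
}

# Covariate fixed-effect terms actually usable in this cohort: categorical
# covariates with a single observed level are dropped (they are aliased
# with the intercept).
covariate_terms <- function(dat) {
  terms <- c("age", "sex", "bmi", "race_ethnicity", "days_since_trauma")
  terms <- terms[terms %in% names(dat)]
  keep <- vapply(terms, function(t) length(unique(dat[[t]])) > 1, logical(1))
  terms[keep]
}

screen_model_frame <- function(panel, species, cohort, outcome) {
  if (!outcome %in% names(panel))
    stop("validation error: outcome '", outcome, "' not in panel")
  if (anyNA(cohort)) stop("validation error: covariates must be complete")
  dat <- merge(panel, cohort, by = "subject_id", sort = FALSE)
  if (nrow(dat) != nrow(panel))
    stop("alignment error: panel subjects missing from cohort")
  dat$.y <- dat[[outcome]]
  dat$.week <- factor(dat$week)
  dat
}

fit_one_lmm <- function(dat, rhs, ctrl) {
  fml <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + "),
                                 "+ (1 | subject_id)"))
  suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = dat, REML = TRUE, control = ctrl)))
}

#' Per-species mixed-model screen with FDR selection
#'
#' For each species, fits `outcome ~ covariates + days_since_trauma +
#' week + asin(sqrt(abundance)) + (1 | subject)` by REML and records the
#' Wald p-value of the abundance term. P-values are Benjamini-Hochberg
#' adjusted across all species; a species is selected when its q-value is
#' at most `fdr_level`. Species whose transformed abundance is constant,
#' or whose fit fails outright, are assigned p = 1 and flagged in the
#' `note` column (they stay in the family so the BH denominator is
#' stable).
#'
#' @param panel long outcome panel (`subject_id`, `week`, outcome columns).
#' @param species a [species_table()], percent scale.
#' @param cohort covariate table (`subject_id`, `sample_id`, `age`, `sex`,
#'   `bmi`, `race_ethnicity`, `days_since_trauma`).
#' @param outcome name of the outcome column in `panel`.
#' @param fdr_level false-discovery level for selection (default 0.05).
#' @return data.frame of class `screen_result`: `feature`, `coefficient`,
#'   `p_value`, `q_value`, `selected`, `note`.
#' @export
screen_features <- function(panel, species, cohort, outcome,
                            fdr_level = 0.05) {
  stopifnot(inherits(species, "species_table"))
  dat <- screen_model_frame(panel, species, cohort, outcome)
  covs <- covariate_terms(dat)
  rhs_base <- c(covs, ".week")
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  prop <- species$values / 100
  sample_of <- match(dat$sample_id, species$samples)

  res <- lapply(species$species, function(sp) {
    a <- arcsine_sqrt(prop[sp, ])[sample_of]
    if (stats::var(a) == 0)
      return(data.frame(feature = sp, coefficient = NA_real_, p_value = 1,
                        note = "constant", stringsAsFactors = FALSE))
    dat$.abund <- a
    fit <- tryCatch(fit_one_lmm(dat, c(rhs_base, ".abund"), ctrl),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(feature = sp, coefficient = NA_real_, p_value = 1,
                        note = "fit_failed", stringsAsFactors = FALSE))
    cf <- summary(fit)$coefficients
    if (!".abund" %in% rownames(cf) || !all(is.finite(cf[".abund", 1:3])))
      return(data.frame(feature = sp, coefficient = NA_real_, p_value = 1,
                        note = "inestimable", stringsAsFactors = FALSE))
    tval <- cf[".abund", "t value"]
    data.frame(feature = sp, coefficient = cf[".abund", "Estimate"],
               p_value = 2 * stats::pnorm(-abs(tval)), note = "",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$selected <- res$q_value <= fdr_level & res$note == ""
  res <- res[, c("feature", "coefficient", "p_value", "q_value",
                 "selected", "note")]
  attr(res, "outcome") <- outcome
  attr(res, "fdr_level") <- fdr_level
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Global mixed model over screened species
#'
#' Combines every selected species into one REML mixed model with the
#' same covariates, categorical week and subject random intercept as the
#' screen. Features whose transformed abundance is linearly dependent on
#' terms already in the design are dropped with a warning.
#'
#' @param screen a `screen_result` from [screen_features()].
#' @param panel,species,cohort,outcome as in [screen_features()].
#' @return object of class `global_lmm`: list with `model` (a `merMod`,
#'   or `NULL` when nothing was selected), `features`, `feature_map`
#'   (safe term name -> species), `outcome`. Zero selected features is a
#'   valid degenerate result, not an error.
#' @export
fit_global_lmm <- function(screen, panel, species, cohort,
                           outcome = attr(screen, "outcome")) {
  stopifnot(inherits(screen, "screen_result"))
  feats <- screen$feature[screen$selected]
  if (length(feats) == 0)
    return(structure(list(model = NULL, features = character(0),
                          feature_map = character(0), outcome = outcome),
                     class = "global_lmm"))
  dat <- screen_model_frame(panel, species, cohort, outcome)
  covs <- covariate_terms(dat)
  sample_of <- match(dat$sample_id, species$samples)
  safe <- paste0(".f", seq_along(feats))
  for (i in seq_along(feats))
    dat[[safe[i]]] <- arcsine_sqrt(species$values[feats[i], ] / 100)[sample_of]

  # drop features aliased with the existing design (rank check)
  keep <- logical(length(feats))
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(c(covs, ".week"), collapse = " + "))),
    dat)
  for (i in seq_along(feats)) {
    cand <- cbind(mm, as.matrix(dat[safe[keep]]), dat[[safe[i]]])
    keep[i] <- qr(cand)$rank == ncol(cand)
  }
  if (!all(keep))
    warning("dropped ", sum(!keep), " aliased feature(s): ",
            paste(feats[!keep], collapse = ", "))
  feats <- feats[keep]; safe <- safe[keep]
  if (nrow(dat) <= length(c(covs, feats)) + nlevels(dat$.week) + 2)
    stop("validation error: too few rows for the global model")

  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- fit_one_lmm(dat, c(covs, ".week", safe), ctrl)
  structure(list(model = fit, features = feats,
                 feature_map = stats::setNames(feats, safe),
                 outcome = outcome),
            class = "global_lmm")
}

#' @export
print.global_lmm <- function(x, ...) {
  if (is.null(x$model)) {
    cat("<global_lmm> no features selected for", x$outcome, "\n")
  } else {
    cat("<global_lmm>", x$outcome, "~", length(x$features),
        "species + covariates, subject random intercept\n")
  }
  invisible(x)
}

#' Sequential sum-of-squares variance partition of a global mixed model
#'
#' Runs sequential (Type I) ANOVA on the fitted global model, with
#' covariates entered before species terms, and expresses each fixed
#' term's sum of squares as a share of the total (fixed sums of squares
#' plus residual sum of squares). The microbiome share is the summed
#' share of all species terms. Fixed-effects-only ratios are reported
#' alongside.
#'
#' @param x a `global_lmm` from [fit_global_lmm()]. The degenerate
#'   no-model result yields an empty partition with microbiome share 0.
#' @return object of class `variance_partition`: data.frame `terms`
#'   (`term`, `ss`, `ratio`, `ratio_fixed`), plus attributes
#'   `residual_ss`, `residual_ratio`, `microbiome_share`.
#' @export
variance_partition <- function(x) {
  stopifnot(inherits(x, "global_lmm"))
  if (is.null(x$model)) {
    terms <- data.frame(term = character(0), ss = numeric(0),
                        ratio = numeric(0), ratio_fixed = numeric(0))
    return(structure(terms, residual_ss = NA_real_, residual_ratio = NA_real_,
                     microbiome_share = 0,
                     class = c("variance_partition", "data.frame")))
  }
  an <- stats::anova(x$model)   # sequential (Type I) for merMod
  ss <- an[, "Sum Sq"]
  term <- rownames(an)
  term[term %in% names(x$feature_map)] <-
    x$feature_map[term[term %in% names(x$feature_map)]]
  resid_ss <- sum(stats::residuals(x$model)^2)
  denom <- sum(ss) + resid_ss
  terms <- data.frame(term = term, ss = ss, ratio = ss / denom,
                      ratio_fixed = ss / sum(ss), stringsAsFactors = FALSE,
                      row.names = NULL)
  structure(terms,
            residual_ss = resid_ss,
            residual_ratio = resid_ss / denom,
            microbiome_share = sum(terms$ratio[terms$term %in% x$features]),
            class = c("variance_partition", "data.frame"))
}

#' Microbiome share of outcome variance
#'
#' @param x a `variance_partition` or `global_lmm`.
#' @return summed variance-ratio of all species terms (0 when no species
#'   were selected).
#' @export
microbiome_share <- function(x) {
  if (inherits(x, "global_lmm")) x <- variance_partition(x)
  stopifnot(inherits(x, "variance_partition"))
  attr(x, "microbiome_share")
}
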