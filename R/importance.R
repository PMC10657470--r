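# Longitudinal evaluation of the MERF: train on week-2/8 outcomes, test
# on unseen week-12 outcomes, repeat over ten seeds, and rank features by
# permutation importance on the held-out rows.

#' Build the MERF feature matrix
#'
#' One row per subject: species relative abundances (proportions) plus
#' clinical covariates (age, female indicator, BMI, race/ethnicity
#' dummies, days since trauma). Species columns are named by terminal
#' species name (`s__` segment), made unique if needed.
#'
#' @param species a [species_table()].
#' @param cohort covariate table with `subject_id` and `sample_id`.
#' @return numeric matrix, subjects x features, rownames = subject ids.
#' @export
merf_features <- function(species, cohort) {
  stopifnot(inherits(species, "species_table"))
  prop <- t(species$values[, cohort$sample_id, drop = FALSE]) / 100
  short <- sub("^.*s__", "s__", species$species)
  colnames(prop) <- make.unique(short)
  covs <- cbind(age = cohort$age,
                sex_female = as.numeric(cohort$sex == "female"),
                bmi = cohort$bmi,
                days_since_trauma = cohort$days_since_trauma)
  race <- stats::model.matrix(~ race_ethnicity,
                              data.frame(race_ethnicity = factor(cohort$race_ethnicity)))[, -1, drop = FALSE]
  X <- cbind(prop, covs, race)
  rownames(X) <- cohort$subject_id
  X
}

#' Longitudinal train/test split
#'
#' Early-week rows (default weeks 2 and 8) train the model; the final
#' week (default 12) is held out for testing — the evaluation mimics
#' forecasting the late outcome from early outcomes and the (stable)
#' microbiome.
#'
#' @param panel long outcome panel with a `week` column.
#' @param train_weeks,test_week week assignments.
#' @return list with `train` and `test` panel subsets (a true partition).
#' @export
time_split <- function(panel, train_weeks = c(2, 8), test_week = 12) {
  train <- panel[panel$week %in% train_weeks, , drop = FALSE]
  test <- panel[panel$week == test_week, , drop = FALSE]
  if (nrow(test) == 0)
    stop("split error: no rows at test week ", test_week)
  if (nrow(train) == 0)
    stop("split error: no rows at training weeks")
  list(train = train, test = test)
}

# Forest-only predictions for a permuted copy of one feature column,
# evaluated in one batched call; random effects are added afterwards and
# therefore held fixed under permutation.
perm_delta <- function(model, x, clusters, y, feature, perm_idx) {
  xp <- x
  xp[, feature] <- xp[perm_idx, feature]
  pred <- predict.merf(model, xp, clusters = clusters)
  mean((y - pred)^2)
}

#' Permutation variable importance on held-out rows
#'
#' For each feature, the mean increase in test MSE over `n_repeats`
#' random permutations of that feature column, with the fitted random
#' intercepts held fixed. Constant columns get importance 0 by
#' convention.
#'
#' @param model fitted [fit_merf()] model.
#' @param x held-out feature rows (matrix/data.frame).
#' @param clusters cluster ids for the held-out rows.
#' @param y held-out responses.
#' @param n_repeats permutations per feature (default 5).
#' @param seed RNG seed for the permutations.
#' @return named numeric vector of mean MSE increases.
#' @export
permutation_importance <- function(model, x, clusters, y, n_repeats = 5,
                                   seed = 0) {
  stopifnot(inherits(model, "merf"))
  x <- as.data.frame(x)[model$features]
  n <- nrow(x)
  base_pred <- predict.merf(model, x, clusters = clusters)
  mse0 <- mean((y - base_pred)^2)
  const <- vapply(x, function(v) length(unique(v)) == 1, logical(1))
  vary <- model$features[!const]

  set.seed(seed)
  perms <- replicate(n_repeats, sample.int(n), simplify = FALSE)
  # one batched forest call over all (feature, repeat) permuted copies
  blocks <- vector("list", length(vary) * n_repeats)
  k <- 0
  for (f in vary) for (p in perms) {
    k <- k + 1
    xp <- x
    xp[[f]] <- xp[[f]][p]
    blocks[[k]] <- xp
  }
  imp <- stats::setNames(rep(0, length(model$features)), model$features)
  if (k > 0) {
    big <- do.call(rbind, blocks)
    pred <- predict.merf(model, big, clusters = rep(clusters, k))
    pm <- matrix(colMeans(matrix((rep(y, k) - pred)^2, nrow = n)),
                 nrow = n_repeats)              # repeats x features
    imp[vary] <- colMeans(pm) - mse0
  }
  imp
}

#' Run the MERF evaluation pipeline over multiple seeds
#'
#' For each seed: fit the MERF on the week-2/8 rows, predict the held-out
#' week-12 rows (subject intercepts are known from training), record test
#' RMSE and Pearson correlation of true versus predicted values, and
#' compute permutation importance on the held-out rows. A failed fit is
#' recorded for that seed and the run continues.
#'
#' @param panel long outcome panel.
#' @param features subject-level feature matrix from [merf_features()].
#' @param outcome outcome column name in `panel`.
#' @param seeds integer seeds (default `0:9`).
#' @param control base [merf_control()]; its seed is replaced per run.
#' @param n_repeats permutation repeats for importance.
#' @param train_weeks,test_week passed to [time_split()].
#' @return list of class `seed_runs`; each element has `seed`,
#'   `rmse_test`, `corr_test`, `importance`, `model` (or `error`).
#' @export
run_seeds <- function(panel, features, outcome, seeds = 0:9,
                      control = merf_control(), n_repeats = 5,
                      train_weeks = c(2, 8), test_week = 12) {
  split <- time_split(panel, train_weeks, test_week)
  get_xy <- function(rows) {
    if (!all(rows$subject_id %in% rownames(features)))
      stop("alignment error: panel subjects missing from feature matrix")
    list(x = features[rows$subject_id, , drop = FALSE],
         cl = rows$subject_id, y = rows[[outcome]])
  }
  tr <- get_xy(split$train); te <- get_xy(split$test)

  runs <- lapply(seeds, function(s) {
    ctl <- control; ctl$seed <- s
    fit <- tryCatch(fit_merf(tr$x, tr$cl, tr$y, ctl), error = identity)
    if (inherits(fit, "condition"))
      return(list(seed = s, error = conditionMessage(fit)))
    pred <- predict.merf(fit, te$x, clusters = te$cl)
    list(seed = s,
         rmse_test = sqrt(mean((te$y - pred)^2)),
         corr_test = suppressWarnings(stats::cor(te$y, pred)),
         importance = permutation_importance(fit, te$x, te$cl, te$y,
                                             n_repeats = n_repeats, seed = s),
         model = fit)
  })
  structure(runs, class = "seed_runs", outcome = outcome)
}

#' Aggregate permutation importance across seeds
#'
#' Mean importance per feature over the seeds where the feature was
#' scored, ranked descending with lexicographic tie-break; only features
#' with positive mean importance are reported, truncated to the top
#' `top_n` (fewer rows when fewer features have signal). When
#' `feature_data` and `outcome_values` are supplied, each feature's
#' direction is added as the Spearman correlation of feature value and
#' outcome across rows.
#'
#' @param runs a `seed_runs` list.
#' @param top_n maximum features reported (default 15).
#' @param feature_data optional row-aligned feature matrix for direction.
#' @param outcome_values optional outcome vector aligned with
#'   `feature_data` rows.
#' @return data.frame of class `importance_table`: `feature`,
#'   `mean_importance`, `rank`, `direction_rho` (NA when no direction
#'   data), `times_in_top15`, `n_seeds`.
#' @export
aggregate_importance <- function(runs, top_n = 15, feature_data = NULL,
                                 outcome_values = NULL) {
  ok <- Filter(function(r) is.null(r$error), runs)
  if (length(ok) == 0) stop("validation error: no successful seed runs")
  feats <- sort(unique(unlist(lapply(ok, function(r) names(r$importance)))))
  mat <- sapply(ok, function(r) r$importance[feats])   # features x seeds
  mat <- matrix(mat, nrow = length(feats), dimnames = list(feats, NULL))
  mean_imp <- rowMeans(mat, na.rm = TRUE)
  n_seeds <- rowSums(!is.na(mat))
  in_top <- rowSums(apply(mat, 2, function(v) {
    r <- rank(-v, ties.method = "first", na.last = "keep")
    !is.na(r) & r <= 15
  }))

  ord <- order(-mean_imp, feats)
  keep <- ord[mean_imp[ord] > 0]
  keep <- keep[seq_len(min(top_n, length(keep)))]
  out <- data.frame(feature = feats[keep],
                    mean_importance = mean_imp[keep],
                    rank = seq_along(keep),
                    direction_rho = NA_real_,
                    times_in_top15 = in_top[keep],
                    n_seeds = n_seeds[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(feature_data) && !is.null(outcome_values)) {
    fd <- as.data.frame(feature_data)
    out$direction_rho <- vapply(out$feature, function(f) {
      if (f %in% names(fd)) feature_direction(fd[[f]], outcome_values)
      else NA_real_
    }, numeric(1))
  }
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Spearman correlation between a feature and an outcome
#'
#' Rank correlation with average-rank tie handling; returns `NA` when
#' either vector has zero variance.
#'
#' @param x feature values.
#' @param y outcome values, same length.
#' @return Spearman's rho, or `NA`.
#' @export
feature_direction <- function(x, y) {
  if (length(x) != length(y)) stop("validation error: length mismatch")
  if (length(x) < 3) stop("validation error: need at least 3 paired values")
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}
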