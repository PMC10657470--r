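test_that("time split partitions weeks 2/8 against week 12", {
  st <- simulate_study(tiny_config())
  sp <- time_split(st$panel)
  expect_equal(nrow(sp$train), 2 * nrow(st$cohort))
  expect_equal(nrow(sp$test), nrow(st$cohort))
  expect_true(all(sp$train$week %in% c(2, 8)))
  expect_true(all(sp$test$week == 12))
  # true partition: no row in both
  key <- function(d) paste(d$subject_id, d$week)
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  # a subject missing week 8 still contributes one train and one test row
  panel2 <- st$panel[!(st$panel$subject_id == st$panel$subject_id[1] &
                         st$panel$week == 8), ]
  sp2 <- time_split(panel2)
  s1 <- st$panel$subject_id[1]
  expect_equal(sum(sp2$train$subject_id == s1), 1)
  expect_equal(sum(sp2$test$subject_id == s1), 1)
  expect_error(time_split(st$panel[st$panel$week != 12, ]), "split error")
})

test_that("permutation importance is zero for identity permutations and constants", {
  st <- simulate_study(tiny_config(seed = 0))
  feats <- merf_features(st$species, st$cohort)
  feats <- cbind(feats, all_same = 1)
  sp <- time_split(st$panel)
  Xtr <- feats[sp$train$subject_id, ]
  m <- fit_merf(Xtr, sp$train$subject_id, sp$train$promis_t,
                fast_merf(seed = 0))
  Xte <- feats[sp$test$subject_id, ]
  # identity permutation leaves the MSE unchanged
  mse0 <- mean((sp$test$promis_t -
                  predict(m, Xte, clusters = sp$test$subject_id))^2)
  d <- gutapns:::perm_delta(m, as.data.frame(Xte)[m$features],
                            sp$test$subject_id, sp$test$promis_t,
                            m$features[1], seq_len(nrow(Xte)))
  expect_equal(d, mse0, tolerance = 1e-12)
  imp <- permutation_importance(m, Xte, sp$test$subject_id,
                                sp$test$promis_t, n_repeats = 2, seed = 1)
  expect_equal(unname(imp["all_same"]), 0)
  expect_equal(names(imp), m$features)
})

test_that("seed runs produce valid metrics and aggregate stably", {
  st <- simulate_study(tiny_config(seed = 0))
  feats <- merf_features(st$species, st$cohort)
  runs <- run_seeds(st$panel, feats, "promis_t", seeds = 0:2,
                    control = fast_merf(), n_repeats = 2)
  expect_length(runs, 3)
  for (r in runs) {
    expect_null(r$error)
    expect_gte(r$rmse_test, 0)
    expect_lte(abs(r$corr_test), 1)
  }
  imp <- aggregate_importance(runs,
                              feature_data = feats[st$panel$subject_id, ],
                              outcome_values = st$panel$promis_t)
  expect_s3_class(imp, "importance_table")
  expect_lte(nrow(imp), 15)
  expect_equal(imp$rank, seq_len(nrow(imp)))
  expect_true(all(imp$mean_importance > 0))
  expect_true(all(diff(imp$mean_importance) <= 0))
  expect_true(all(abs(imp$direction_rho) <= 1, na.rm = TRUE))
  # aggregation is invariant to the order of seed results
  imp_rev <- aggregate_importance(rev(runs),
                                  feature_data = feats[st$panel$subject_id, ],
                                  outcome_values = st$panel$promis_t)
  expect_equal(imp_rev, imp)
  # single-seed aggregation degenerates gracefully
  imp1 <- aggregate_importance(runs[1])
  expect_true(all(imp1$n_seeds == 1))
})

test_that("identical per-seed importances aggregate to themselves", {
  v <- c(a = 0.5, b = 0.2, c = 0)
  runs <- structure(list(list(seed = 1, importance = v),
                         list(seed = 2, importance = v)),
                    class = "seed_runs")
  imp <- aggregate_importance(runs)
  expect_equal(imp$feature, c("a", "b"))  # zero-importance feature dropped
  expect_equal(imp$mean_importance, c(0.5, 0.2))
  # ties break lexicographically
  runs2 <- structure(list(list(seed = 1,
                               importance = c(z = 0.3, m = 0.3, k = 0.3))),
                     class = "seed_runs")
  expect_equal(aggregate_importance(runs2)$feature, c("k", "m", "z"))
})

test_that("a seed with a failed fit is recorded and skipped in aggregation", {
  v <- c(a = 0.4, b = 0.1)
  runs <- structure(list(list(seed = 1, importance = v),
                         list(seed = 2, error = "boom")),
                    class = "seed_runs")
  imp <- aggregate_importance(runs)
  expect_equal(imp$n_seeds, c(1, 1))
  expect_equal(imp$mean_importance, c(0.4, 0.1))
})

test_that("feature direction is Spearman correlation with tie handling", {
  expect_equal(feature_direction(1:10, (1:10)^3), 1)
  expect_equal(feature_direction(1:10, -(1:10)), -1)
  # hand-computed from the rank formula: d^2 sums to 4,
  # rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(feature_direction(1:5, c(2, 1, 4, 3, 5)), 0.8)
  expect_true(is.na(feature_direction(rep(1, 5), 1:5)))
  expect_error(feature_direction(1:2, 1:2), "at least 3")
  expect_error(feature_direction(1:4, 1:5), "length mismatch")
})

test_that("duplicating a feature column splits its importance under bagging", {
  # mtry = p so both copies compete at every split and dilute each other;
  # under feature subsampling a duplicated copy raises the chance the
  # forest uses the signal at all, which can inflate, not split, the
  # importance (a known artifact of permutation importance under
  # correlated features)
  st <- simulate_study(sim_config(n_subjects = 40, n_species = 60, seed = 0))
  feats <- merf_features(st$species, st$cohort)
  dom <- sub("^.*s__", "s__", st$truth$effectors[1])
  sp <- time_split(st$panel)
  fit_imp <- function(X, seed) {
    m <- fit_merf(X[sp$train$subject_id, ], sp$train$subject_id,
                  sp$train$promis_t,
                  merf_control(n_trees = 150, max_iter = 8, seed = seed,
                               mtry = ncol(X)))
    permutation_importance(m, X[sp$test$subject_id, ], sp$test$subject_id,
                           sp$test$promis_t, n_repeats = 5, seed = seed)
  }
  seeds <- 0:1
  solo <- mean(vapply(seeds, function(s) fit_imp(feats, s)[dom], numeric(1)))
  dup <- rowMeans(vapply(seeds, function(s) {
    d <- fit_imp(cbind(feats, dom_copy = feats[, dom]), s)
    c(d[dom], d["dom_copy"])
  }, numeric(2)))
  expect_lt(dup[1], solo)
  expect_lt(dup[2], solo)
})
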