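test_that("arcsine square root transform has its closed-form values", {
  expect_equal(arcsine_sqrt(0), 0)
  expect_equal(arcsine_sqrt(1), pi / 2)
  expect_equal(arcsine_sqrt(0.25), pi / 6)
  expect_equal(arcsine_sqrt(c(0, 0.5, 1)), asin(sqrt(c(0, 0.5, 1))))
  expect_error(arcsine_sqrt(1.01), "domain error")
  expect_error(arcsine_sqrt(-0.01), "domain error")
  expect_equal(arcsine_sqrt(1 + 1e-13), pi / 2)  # clamped within tolerance
})

test_that("the screen selects a strongly planted effector and flags constant species", {
  st <- simulate_study(sim_config(seed = 0))
  # add a constant-zero species to the table
  vals <- rbind(st$species$values, 0)
  rownames(vals)[nrow(vals)] <- "k__Bacteria|g__Z|s__Z_null"
  sp <- species_table(vals)
  scr <- screen_features(st$panel, sp, st$cohort, "promis_t")
  expect_s3_class(scr, "screen_result")
  expect_true(scr$selected[scr$feature == st$truth$effectors[1]])
  con <- scr[scr$feature == "k__Bacteria|g__Z|s__Z_null", ]
  expect_equal(con$p_value, 1)
  expect_equal(con$note, "constant")
  expect_false(con$selected)
  # BH: q-values never below p-values, and selection respects the level
  expect_true(all(scr$q_value >= scr$p_value - 1e-12))
  expect_true(all(scr$q_value[scr$selected] <= 0.05))
})

test_that("the screen is invariant to species row order", {
  st <- simulate_study(tiny_config(seed = 3))
  scr1 <- screen_features(st$panel, st$species, st$cohort, "promis_t")
  perm <- rev(seq_along(st$species$species))
  sp2 <- species_table(st$species$values[perm, ])
  scr2 <- screen_features(st$panel, sp2, st$cohort, "promis_t")
  m <- match(scr1$feature, scr2$feature)
  expect_equal(scr2$p_value[m], scr1$p_value, tolerance = 1e-10)
  expect_equal(scr2$selected[m], scr1$selected)
})

test_that("with sigma_b = 0 the mixed-model screen agrees with OLS", {
  # no planted effects: residual between-subject signal from omitted
  # effectors would otherwise surface as random-intercept variance
  cfg <- sim_config(n_subjects = 80, n_species = 25, sigma_b = 0, seed = 5,
                    effect_sizes = rep(0, 5))
  st <- simulate_study(cfg)
  scr <- screen_features(st$panel, st$species, st$cohort, "promis_t")
  dat <- merge(st$panel, st$cohort, by = "subject_id")
  prop <- st$species$values / 100
  idx <- match(dat$sample_id, st$species$samples)
  p_ols <- vapply(st$species$species, function(sp) {
    dat$.a <- arcsine_sqrt(prop[sp, ])[idx]
    fit <- lm(promis_t ~ age + sex + bmi + race_ethnicity +
                days_since_trauma + factor(week) + .a, data = dat)
    tv <- summary(fit)$coefficients[".a", "t value"]
    2 * pnorm(-abs(tv))
  }, numeric(1))
  ok <- p_ols > 1e-8   # relative agreement is meaningless at underflow
  rel <- abs(scr$p_value[ok] - p_ols[ok]) / p_ols[ok]
  expect_lt(stats::median(rel), 0.1)
  expect_lt(mean(rel > 0.1), 0.2)
})

test_that("a single selected feature gives a global model matching its screen fit", {
  st <- simulate_study(tiny_config(seed = 0))
  scr <- screen_features(st$panel, st$species, st$cohort, "promis_t")
  # restrict selection to the top feature only
  scr$selected <- scr$feature == scr$feature[which.min(scr$q_value)]
  gl <- fit_global_lmm(scr, st$panel, st$species, st$cohort)
  expect_length(gl$features, 1)
  cf_global <- lme4::fixef(gl$model)[".f1"]
  expect_equal(unname(cf_global),
               scr$coefficient[scr$selected], tolerance = 1e-6)
})

test_that("zero selected features yields an explicit no-model result with share 0", {
  st <- simulate_study(tiny_config(seed = 1))
  scr <- screen_features(st$panel, st$species, st$cohort, "promis_t")
  scr$selected <- rep(FALSE, nrow(scr))
  gl <- fit_global_lmm(scr, st$panel, st$species, st$cohort)
  expect_null(gl$model)
  vp <- variance_partition(gl)
  expect_equal(microbiome_share(vp), 0)
  expect_equal(nrow(vp), 0)
})

test_that("planted effectors recover their signs in the global model", {
  cfg <- sim_config(seed = 0)
  st <- simulate_study(cfg)
  scr <- screen_features(st$panel, st$species, st$cohort, "promis_t")
  gl <- fit_global_lmm(scr, st$panel, st$species, st$cohort)
  hits <- intersect(gl$features, st$truth$effectors)
  expect_gte(length(hits), 1)
  cf <- lme4::fixef(gl$model)
  for (h in hits) {
    safe <- names(gl$feature_map)[gl$feature_map == h]
    expect_gt(cf[safe] * st$truth$effect_sizes[h], 0)
  }
})

test_that("variance partition ratios are nonnegative and sum to one", {
  st <- simulate_study(tiny_config(seed = 0))
  scr <- screen_features(st$panel, st$species, st$cohort, "promis_t")
  # force a three-feature selection so the partition is non-degenerate
  scr$selected <- rank(scr$p_value, ties.method = "first") <= 3
  gl <- fit_global_lmm(scr, st$panel, st$species, st$cohort)
  vp <- variance_partition(gl)
  expect_true(all(vp$ratio >= 0))
  expect_equal(sum(vp$ratio) + attr(vp, "residual_ratio"), 1,
               tolerance = 1e-9)
  expect_equal(sum(vp$ratio_fixed), 1, tolerance = 1e-9)
  expect_equal(microbiome_share(vp),
               sum(vp$ratio[vp$term %in% gl$features]))
})
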