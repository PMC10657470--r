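# Simulated clustered data for the MERF engine tests
make_clustered <- function(n_cl = 30, n_per = 3, p = 8, sigma_b = 2,
                           sigma_e = 1, beta = NULL, seed = 1) {
  set.seed(seed)
  n <- n_cl * n_per
  X <- matrix(rnorm(n_cl * p), n_cl, p)[rep(seq_len(n_cl), each = n_per), ]
  colnames(X) <- paste0("x", seq_len(p))
  b <- rnorm(n_cl, 0, sigma_b)
  cl <- rep(sprintf("C%02d", seq_len(n_cl)), each = n_per)
  f <- if (is.null(beta)) rep(0, n) else as.numeric(X %*% beta)
  list(X = X, cl = cl, b = b, f = f,
       y = f + b[rep(seq_len(n_cl), each = n_per)] + rnorm(n, 0, sigma_e))
}

test_that("fit_merf validates its inputs", {
  d <- make_clustered()
  expect_error(fit_merf(d$X, rep("one", nrow(d$X)), d$y, fast_merf()),
               "degenerate design")
  expect_error(fit_merf(d$X, d$cl, c(d$y[-1], NA), fast_merf()),
               "non-finite")
  expect_error(fit_merf(d$X[1:10, ], d$cl, d$y, fast_merf()),
               "matching rows")
})

test_that("max_iter = 1 returns an unconverged single-iteration model", {
  d <- make_clustered()
  m <- fit_merf(d$X, d$cl, d$y, merf_control(n_trees = 50, max_iter = 1))
  expect_equal(m$n_iter, 1)
  expect_false(m$converged)
  expect_length(m$gll_trace, 1)
  expect_true(all(is.finite(m$gll_trace)))
})

test_that("pure random-intercept data recovers the intercepts and variances", {
  d <- make_clustered(n_cl = 50, n_per = 3, p = 10, sigma_b = 2,
                      sigma_e = 1, seed = 0)
  m <- fit_merf(d$X, d$cl, d$y, merf_control(n_trees = 150, max_iter = 15,
                                             seed = 0))
  expect_gte(cor(m$b_hat, d$b), 0.8)
  expect_gt(m$sigma2_b, 1)   # truth 4; order of magnitude, not collapsed
  expect_true(all(is.finite(m$gll_trace)))
})

test_that("data without cluster effects yields near-zero sigma2_b and intercepts", {
  # row-varying features: with cluster-constant features any forest
  # lack-of-fit is itself cluster-structured and shows up as intercepts
  set.seed(0)
  n_cl <- 40; n_per <- 3; n <- n_cl * n_per
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("x", 1:6)))
  cl <- rep(sprintf("C%02d", seq_len(n_cl)), each = n_per)
  y <- X[, 1] - X[, 2] + rnorm(n, 0, 1)
  m <- fit_merf(X, cl, y, merf_control(n_trees = 150, max_iter = 15,
                                       seed = 0))
  expect_lte(m$sigma2_b, 0.1 * m$sigma2_e)
  expect_lte(max(abs(m$b_hat)), 0.2 * sqrt(m$sigma2_e))
})

test_that("linear-learner MERF variances agree with REML on linear data", {
  d <- make_clustered(n_cl = 60, n_per = 4, p = 4, sigma_b = 1.5,
                      sigma_e = 1, beta = c(2, -1, 0.5, 0), seed = 2)
  m <- fit_merf(d$X, d$cl, d$y,
                merf_control(learner = "linear", max_iter = 60, tol = 1e-8))
  ref <- lme4::lmer(y ~ x + (1 | cl),
                    data = data.frame(y = d$y, x = I(d$X), cl = d$cl),
                    REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(ref))
  s2b_ref <- vc$vcov[vc$grp == "cl"]
  s2e_ref <- vc$vcov[vc$grp == "Residual"]
  expect_lt(abs(m$sigma2_b - s2b_ref) / s2b_ref, 0.25)
  expect_lt(abs(m$sigma2_e - s2e_ref) / s2e_ref, 0.25)
})

test_that("predictions add the known-cluster intercept and nothing else", {
  d <- make_clustered(seed = 4)
  m <- fit_merf(d$X, d$cl, d$y, fast_merf(seed = 1))
  fixed <- predict(m, d$X)
  known <- predict(m, d$X, clusters = d$cl)
  expect_equal(known - fixed, unname(m$b_hat[d$cl]))
  # unseen clusters fall back to the forest prediction
  expect_equal(predict(m, d$X, clusters = rep("NEW", nrow(d$X))), fixed)
  # row-wise equivariance under permutation
  perm <- sample(nrow(d$X))
  expect_equal(predict(m, d$X[perm, ], clusters = d$cl[perm]), known[perm])
  expect_error(predict(m, d$X[, 1:3]), "columns")
})

test_that("fitting is deterministic given seed, data and hyperparameters", {
  d <- make_clustered(seed = 6)
  m1 <- fit_merf(d$X, d$cl, d$y, fast_merf(seed = 3))
  m2 <- fit_merf(d$X, d$cl, d$y, fast_merf(seed = 3))
  expect_identical(m1$gll_trace, m2$gll_trace)
  expect_identical(m1$b_hat, m2$b_hat)
  expect_equal(predict(m1, d$X, clusters = d$cl),
               predict(m2, d$X, clusters = d$cl))
})

test_that("GLL matches an independently coded closed form on a toy cluster", {
  # 3-row single-cluster toy evaluated directly from the definition
  y <- c(1.0, 2.0, 0.5)
  fhat <- c(0.8, 1.6, 0.7)
  b <- 0.3
  s2e <- 0.5
  s2b <- 2.0
  # independent evaluation: explicit sums, no shared code path
  eps <- (1.0 - 0.8 - 0.3)^2 + (2.0 - 1.6 - 0.3)^2 + (0.5 - 0.7 - 0.3)^2
  oracle <- eps / 0.5 + 0.3^2 / 2.0 + 3 * log(0.5) + 1 * log(2.0)
  expect_equal(gll_value(y, fhat, b, rep("c1", 3), s2e, s2b), oracle,
               tolerance = 1e-8)
  # sigma2_b = 0 omits the random-effect penalty
  oracle0 <- ((1 - 0.8)^2 + (2 - 1.6)^2 + (0.5 - 0.7)^2) / 0.5 + 3 * log(0.5)
  expect_equal(gll_value(y, fhat, 0, rep("c1", 3), 0.5, 0), oracle0)
})

test_that("GLL decreases with residuals and increases when residuals double", {
  y <- c(1, 2, 3, 4)
  cl <- c("a", "a", "b", "b")
  b <- c(0.1, -0.1)
  g_small <- gll_value(y, y - 0.1, b, cl, 1, 1)
  g_large <- gll_value(y, y - 0.2, b, cl, 1, 1)
  expect_lt(g_small, g_large)
  # shrinking sigma2_e under a perfect fit drives GLL down
  expect_lt(gll_value(y, y, c(0, 0), cl, 1e-6, 1),
            gll_value(y, y, c(0, 0), cl, 1, 1))
})

test_that("gll() on a fitted model equals gll_value on its components", {
  d <- make_clustered(seed = 8)
  m <- fit_merf(d$X, d$cl, d$y, fast_merf(seed = 2))
  fhat <- predict(m, d$X)
  expect_equal(gll(m, d$X, d$cl, d$y),
               gll_value(d$y, fhat, m$b_hat, d$cl, m$sigma2_e, m$sigma2_b))
})
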