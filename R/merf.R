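# Mixed-effect random forest (MERF) for clustered longitudinal data.
# The fixed part is a regression forest, the random part a per-cluster
# (per-subject) intercept; the two are alternated by EM: the forest is
# fit on the working response y - Zb, the intercepts are re-estimated as
# BLUPs given the current variance components, and the variance
# components are updated by the standard EM formulas. Convergence is
# monitored on a generalized log-likelihood (GLL).
#
# Two departures from the classical alternation, both forced by the
# supported study design (one microbiome sample per subject, so every
# feature is constant within a cluster):
#
# 1. Variance components are re-estimated HONESTLY after the
#    alternation: residuals are taken against cluster-level out-of-bag
#    predictions (only trees whose bootstrap contains no row of the
#    row's cluster; row-level OOB is not enough because a subject's
#    rows share identical features), and the random-intercept EM is run
#    to convergence on them with the forest fixed. In-sample residuals
#    would collapse sigma2_b, because bootstrap memorization absorbs
#    most cluster structure into the trees.
#
# 2. The alternation cap defaults to a single pass. When all features
#    are cluster-constant, subtracting the BLUP from the working
#    response removes the between-subject variation that carries the
#    entire feature signal, so every additional pass drains
#    generalizable signal out of the forest and into the intercepts
#    regardless of how the residuals are evaluated; there is no
#    identifiable optimum for the alternation to find. With
#    longitudinally varying features the alternation behaves as usual
#    and `max_iter` can be raised.
#
# The intercepts used for prediction are the BLUPs of the in-sample
# residuals at the honest variance components: they complement what
# the forest actually predicts for a seen cluster (which already
# carries part of that cluster's effect), so forest + intercept does
# not double-count.

#' MERF hyperparameters
#'
#' @param n_trees trees per forest refit (default 300).
#' @param mtry features tried per split; `NULL` means the regression
#'   heuristic `ceiling(p/3)`.
#' @param min_leaf minimum terminal-node size (default 3).
#' @param max_iter EM alternation cap. The default of 1 (single forest
#'   fit, no working-response subtraction) is deliberate: with
#'   cluster-constant features, further alternation only transfers
#'   generalizable feature signal into the intercepts (see Details).
#'   Raise it for designs whose features vary within cluster.
#' @param tol relative GLL change declaring convergence (default 1e-4).
#' @param seed integer seed controlling all forest randomness.
#' @param learner `"forest"` (default) or `"linear"`; the linear learner
#'   replaces the forest with ordinary least squares on the same working
#'   response, which is useful for validating the EM variance updates
#'   against a standard mixed-model fitter (no honest correction is
#'   applied: least squares does not memorize clusters).
#' @return list of class `merf_control`.
#' @export
merf_control <- function(n_trees = 300, mtry = NULL, min_leaf = 3,
                         max_iter = 1, tol = 1e-4, seed = 0,
                         learner = c("forest", "linear")) {
  learner <- match.arg(learner)
  stopifnot(n_trees >= 1, min_leaf >= 1, max_iter >= 1, tol > 0)
  structure(list(n_trees = n_trees, mtry = mtry, min_leaf = min_leaf,
                 max_iter = max_iter, tol = tol, seed = seed,
                 learner = learner),
            class = "merf_control")
}

# Cluster-level OOB predictions from a ranger fit with inbag counts
# retained. Rows of clusters with no fully-held-out tree fall back to
# the overall mean of the training response.
cluster_oob_predictions <- function(fit, x_df, cluster_idx, ystar) {
  per_tree <- stats::predict(fit, data = x_df, predict.all = TRUE,
                             num.threads = 1)$predictions
  inbag <- matrix(unlist(fit$inbag.counts), nrow = nrow(x_df))
  cl_inbag <- rowsum(inbag, cluster_idx) > 0      # cluster x tree
  fallback <- mean(ystar)
  fhat <- numeric(nrow(x_df))
  for (i in seq_len(nrow(x_df))) {
    ok <- !cl_inbag[cluster_idx[i], ]
    fhat[i] <- if (any(ok)) mean(per_tree[i, ok]) else fallback
  }
  fhat
}

fit_fixed_learner <- function(x_df, ystar, ctl, iter_seed) {
  if (ctl$learner == "linear") {
    fit <- stats::lm.fit(cbind(1, as.matrix(x_df)), ystar)
    list(fit = list(coef = fit$coefficients), fhat = fit$fitted.values)
  } else {
    mtry <- if (is.null(ctl$mtry)) ceiling(ncol(x_df) / 3) else ctl$mtry
    fit <- ranger::ranger(y = ystar, x = x_df, num.trees = ctl$n_trees,
                          mtry = mtry, min.node.size = ctl$min_leaf,
                          seed = iter_seed, num.threads = 1,
                          keep.inbag = TRUE)
    list(fit = fit,
         fhat = stats::predict(fit, data = x_df,
                               num.threads = 1)$predictions)
  }
}

# Random-intercept EM with the fixed part held fixed: given residuals
# r = y - f(X), iterate BLUP and the standard variance updates to
# convergence. A proper (monotone) EM for the Gaussian intercept model.
intercept_em <- function(r, ci, ni, s2e = 1, s2b = 1, tol = 1e-8,
                         max_iter = 1000) {
  N <- length(r); q <- length(ni)
  sr <- rowsum(r, ci)[, 1]
  b <- rep(0, q)
  for (k in seq_len(max_iter)) {
    b <- if (s2b > 0) s2b * sr / (s2e + ni * s2b) else rep(0, q)
    eps <- r - b[ci]
    den <- s2e + ni * s2b
    s2e_new <- (sum(eps^2) + sum(s2e * ni * s2b / den)) / N
    s2b_new <- (sum(b^2) + sum(s2b * s2e / den)) / q
    delta <- max(abs(s2e_new - s2e) / s2e,
                 abs(s2b_new - s2b) / max(s2b, 1e-12))
    s2e <- s2e_new; s2b <- s2b_new
    if (s2b < 1e-10) s2b <- 0
    if (delta < tol) break
  }
  list(b = b, s2e = s2e, s2b = s2b)
}

#' Fit a mixed-effect random forest
#'
#' EM alternation between a regression forest on the working response
#' `y - b[cluster]` and BLUP estimation of per-cluster random
#' intercepts. Starting from `b = 0`, `sigma2_e = sigma2_b = 1`, each
#' iteration (i) refits the learner, (ii) sets
#' `b_i = sigma2_b * sum(r_i) / (sigma2_e + n_i * sigma2_b)` from the
#' cluster residuals `r_i = y_i - f(X_i)`, (iii) applies the EM variance
#' updates, and (iv) evaluates the GLL; the alternation stops when the
#' relative GLL change drops below `tol` or at `max_iter`.
#'
#' For the forest learner, the variance components reported in the
#' fitted model are then re-estimated honestly — the random-intercept
#' EM is run to convergence on residuals against cluster-level
#' out-of-bag predictions of the final forest (in-sample forest
#' residuals absorb most cluster structure into the trees and collapse
#' `sigma2_b`) — and `b_hat` is the BLUP of the in-sample residuals at
#' those honest variance components, so that forest prediction plus
#' intercept does not double-count cluster effects. The forest itself,
#' and hence feature attribution, is left untouched.
#'
#' @param x feature matrix or data.frame (rows aligned with `y`).
#' @param clusters cluster (subject) identifier per row; at least two
#'   distinct clusters are required.
#' @param y numeric response.
#' @param control a [merf_control()].
#' @return object of class `merf`: `forest`, `b_hat` (named per cluster),
#'   `sigma2_e`, `sigma2_b`, `gll_trace`, `n_iter`, `converged`,
#'   `features`, `control`.
#' @export
fit_merf <- function(x, clusters, y, control = merf_control()) {
  stopifnot(inherits(control, "merf_control"))
  x_df <- as.data.frame(x)
  if (is.null(colnames(x))) names(x_df) <- paste0("V", seq_len(ncol(x_df)))
  if (nrow(x_df) != length(y) || length(clusters) != length(y))
    stop("validation error: x, clusters and y must have matching rows")
  if (any(!is.finite(y))) stop("validation error: non-finite response")
  clf <- factor(clusters)
  if (nlevels(clf) < 2)
    stop("degenerate design: need at least two clusters")
  if (length(y) < 4) stop("degenerate design: too few rows")
  ci <- as.integer(clf)
  ni <- tabulate(ci)
  N <- length(y); q <- nlevels(clf)

  b <- rep(0, q); s2e <- 1; s2b <- 1
  trace <- numeric(0); converged <- FALSE; learner <- NULL
  for (it in seq_len(control$max_iter)) {
    ystar <- y - b[ci]
    lf <- fit_fixed_learner(x_df, ystar, control, control$seed + it)
    learner <- lf$fit
    r <- y - lf$fhat
    sr <- rowsum(r, ci)[, 1]
    b <- if (s2b > 0) s2b * sr / (s2e + ni * s2b) else rep(0, q)
    eps <- r - b[ci]
    den <- s2e + ni * s2b
    s2e_new <- (sum(eps^2) + sum(s2e * ni * s2b / den)) / N
    s2b_new <- (sum(b^2) + sum(s2b * s2e / den)) / q
    s2e <- s2e_new; s2b <- s2b_new
    if (s2b < 1e-10) s2b <- 0
    g <- gll_value(y, lf$fhat, b, clf, s2e, s2b)
    trace <- c(trace, g)
    if (it > 1 && abs(g - trace[it - 1]) / max(abs(g), 1e-10) < control$tol) {
      converged <- TRUE
      break
    }
  }

  if (control$learner == "forest") {
    fhat_in <- stats::predict(learner, data = x_df,
                              num.threads = 1)$predictions
    fhat_honest <- cluster_oob_predictions(learner, x_df, ci, y - b[ci])
    est <- intercept_em(y - fhat_honest, ci, ni)
    s2e <- est$s2e; s2b <- est$s2b
    # prediction intercepts: BLUP of what the forest does NOT already
    # reproduce for each seen cluster, shrunk at the honest components
    r_in <- rowsum(y - fhat_in, ci)[, 1]
    b <- if (s2b > 0) s2b * r_in / (s2e + ni * s2b) else rep(0, q)
  }
  structure(list(forest = learner, b_hat = stats::setNames(b, levels(clf)),
                 sigma2_e = s2e, sigma2_b = s2b, gll_trace = trace,
                 n_iter = length(trace), converged = converged,
                 features = names(x_df), control = control),
            class = "merf")
}

#' @export
print.merf <- function(x, ...) {
  cat("<merf> ", length(x$b_hat), " clusters | sigma2_e = ",
      signif(x$sigma2_e, 4), ", sigma2_b = ", signif(x$sigma2_b, 4),
      " | ", x$n_iter, " EM iterations (",
      if (x$converged) "converged" else "iteration cap", ")\n", sep = "")
  invisible(x)
}

#' Predict from a fitted MERF
#'
#' Forest prediction plus the estimated random intercept for clusters
#' seen in training; unseen clusters (or `clusters = NULL`) receive the
#' forest prediction alone.
#'
#' @param object a fitted `merf`.
#' @param newdata feature matrix/data.frame with the training columns.
#' @param clusters optional cluster id per row.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.merf <- function(object, newdata, clusters = NULL, ...) {
  x_df <- as.data.frame(newdata)
  if (is.null(colnames(newdata)))
    names(x_df) <- paste0("V", seq_len(ncol(x_df)))
  if (!identical(names(x_df), object$features)) {
    if (!all(object$features %in% names(x_df)))
      stop("validation error: newdata columns do not match training features")
    x_df <- x_df[object$features]
  }
  fixed <- if (object$control$learner == "linear") {
    as.numeric(cbind(1, as.matrix(x_df)) %*% object$forest$coef)
  } else {
    stats::predict(object$forest, data = x_df, num.threads = 1)$predictions
  }
  if (is.null(clusters)) return(fixed)
  boff <- object$b_hat[as.character(clusters)]
  boff[is.na(boff)] <- 0
  fixed + as.numeric(boff)
}

#' Generalized log-likelihood of residuals and random effects
#'
#' The MERF convergence criterion (lower is better), up to additive
#' constants:
#' `sum_i [ ||y_i - f_i - b_i||^2 / sigma2_e + b_i^2 / sigma2_b ] +
#'  N log sigma2_e + q log sigma2_b`.
#' When `sigma2_b = 0` the random-effect penalty terms are omitted (the
#' degenerate no-intercept limit).
#'
#' @param y response vector.
#' @param fhat fixed-part predictions per row.
#' @param b random intercept per cluster (vector aligned with the levels
#'   of `clusters`).
#' @param clusters cluster id per row.
#' @param sigma2_e,sigma2_b variance components (`sigma2_e > 0`).
#' @return scalar GLL.
#' @export
gll_value <- function(y, fhat, b, clusters, sigma2_e, sigma2_b) {
  stopifnot(sigma2_e > 0, sigma2_b >= 0)
  clf <- factor(clusters)
  eps <- y - fhat - b[as.integer(clf)]
  g <- sum(eps^2) / sigma2_e + length(y) * log(sigma2_e)
  if (sigma2_b > 0)
    g <- g + sum(b^2) / sigma2_b + nlevels(clf) * log(sigma2_b)
  g
}

#' Evaluate the GLL of a fitted MERF on data
#'
#' @param model fitted `merf`.
#' @param x feature matrix/data.frame.
#' @param clusters cluster id per row; clusters unseen in training
#'   contribute zero random effect.
#' @param y response.
#' @return scalar GLL (see [gll_value()]).
#' @export
gll <- function(model, x, clusters, y) {
  stopifnot(inherits(model, "merf"))
  fhat <- predict.merf(model, x, clusters = NULL)
  clf <- factor(clusters)
  b <- model$b_hat[levels(clf)]
  b[is.na(b)] <- 0
  gll_value(y, fhat, b, clf, model$sigma2_e, model$sigma2_b)
}
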