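#' Wald (covariance-ratio) effect estimate on residuals
#'
#' The local 2SLS estimate `Cov(Ytil, Ztil) / Cov(Dtil, Ztil)` used inside
#' every leaf of the instrumental forest and, on uncentred data, equal to
#' the classical Wald ratio (ITT over first stage). When the denominator
#' covariance is below 1e-10 in absolute value a degenerate marker
#' (`NA` with attribute `degenerate = TRUE`) is returned.
#'
#' @param yt,dt,zt Residualised outcome, treatment and instrument vectors
#'   of equal length (at least 2). Uncentred vectors give the unconditional
#'   Wald estimate since centring cancels in the covariance ratio.
#' @return Scalar effect value, or a degenerate marker.
#' @export
leaf_wald <- function(yt, dt, zt) {
  n <- length(yt)
  if (n < 2 || length(dt) != n || length(zt) != n)
    stopf("leaf_wald: need equal-length vectors of length >= 2")
  den <- cov_n(dt, zt)
  if (abs(den) < 1e-10)
    return(structure(NA_real_, degenerate = TRUE))
  cov_n(yt, zt) / den
}

#' Weight-averaged Wald estimate
#'
#' Solves the alpha-weighted moment condition of the instrumental forest
#' explicitly: the w-weighted covariance ratio of (yt, zt) to (dt, zt).
#' With uniform weights this reduces to [leaf_wald()].
#'
#' @param yt,dt,zt Residual vectors.
#' @param w Non-negative weights (normalised internally).
#' @return Scalar effect value or degenerate `NA` marker.
#' @export
weighted_wald <- function(yt, dt, zt, w) {
  w <- w / sum(w)
  cyz <- sum(w * yt * zt) - sum(w * yt) * sum(w * zt)
  cdz <- sum(w * dt * zt) - sum(w * dt) * sum(w * zt)
  if (abs(cdz) < 1e-10) return(structure(NA_real_, degenerate = TRUE))
  cyz / cdz
}

#' Estimate nuisance functions by out-of-bag regression forests
#'
#' Fits three honest regression forests — for the conditional outcome mean
#' m(x) = E(Y | X), the treatment propensity e(x) = P(D = 1 | X) and the
#' instrument propensity g(x) = P(Z = 1 | X) — and returns their
#' out-of-bag predictions. When `exclude_supply_from_e` is set (the
#' default), the e(x) forest never sees the supply-tagged columns, because
#' in designs where supply-side readiness determines eligibility those
#' columns are part of the assignment mechanism rather than confounders.
#' Propensities are clipped to [0.01, 0.99]; m(x) is clipped to the
#' observed outcome range.
#'
#' @param ds A [trial_dataset()].
#' @param params A [forest_params()]; sub-seeds for the three forests are
#'   derived from `params$seed`.
#' @param exclude_supply_from_e Drop supply-tagged columns from the
#'   treatment-propensity forest.
#' @return An object of class `nuisances` with `m_hat`, `e_hat`, `g_hat`,
#'   the three fitted forests, and clipping bookkeeping.
#' @export
estimate_nuisances <- function(ds, params = forest_params(),
                               exclude_supply_from_e = TRUE) {
  stopifnot(inherits(ds, "trial_dataset"))
  if (exclude_supply_from_e && length(ds$supply_tags) == 0)
    stopf(paste("estimate_nuisances: exclude_supply_from_e is set but the",
                "dataset has no supply-tagged columns; tag them in",
                "trial_dataset() or pass exclude_supply_from_e = FALSE"))
  Xe <- if (exclude_supply_from_e) {
    ds$X[, setdiff(colnames(ds$X), ds$supply_tags), drop = FALSE]
  } else ds$X
  if (ncol(Xe) == 0)
    stopf("estimate_nuisances: no covariates left for the e(x) forest")

  pseed <- function(k) { p <- params; p$seed <- as.integer(sub_seed(params$seed, k)); p }
  m_forest <- regression_forest(ds$X, ds$y, pseed(11))
  e_forest <- regression_forest(Xe, ds$d, pseed(12))
  g_forest <- regression_forest(ds$X, ds$z, pseed(13))

  m_hat <- predict_oob(m_forest)
  e_raw <- predict_oob(e_forest)
  g_raw <- predict_oob(g_forest)
  rng <- range(ds$y)
  structure(
    list(m_hat = pmin(pmax(m_hat, rng[1]), rng[2]),
         e_hat = clip01(e_raw), g_hat = clip01(g_raw),
         m_forest = m_forest, e_forest = e_forest, g_forest = g_forest,
         clipped = list(e = which(e_raw < 0.01 | e_raw > 0.99),
                        g = which(g_raw < 0.01 | g_raw > 0.99)),
         exclude_supply_from_e = exclude_supply_from_e),
    class = "nuisances")
}

#' Residualise outcome, treatment and instrument
#'
#' Elementwise `Ytil = Y - m_hat`, `Dtil = D - e_hat`, `Ztil = Z - g_hat`,
#' the orthogonalised inputs of the instrumental forest.
#'
#' @param ds A [trial_dataset()].
#' @param nu A [estimate_nuisances()] result fitted on the same units.
#' @return List with `ytil`, `dtil`, `ztil`.
#' @export
residualise <- function(ds, nu) {
  stopifnot(inherits(ds, "trial_dataset"), inherits(nu, "nuisances"))
  if (length(nu$m_hat) != ds$n)
    stopf("residualise: nuisance estimates do not match the dataset")
  list(ytil = ds$y - nu$m_hat, dtil = ds$d - nu$e_hat, ztil = ds$z - nu$g_hat)
}

#' Fit an instrumental causal forest
#'
#' Grows honest trees on the residualised data. At each parent node the
#' local Wald estimate `tau_p` is computed and each structure-half unit is
#' given the gradient pseudo-outcome
#' `rho_i = Ztil_i (Ytil_i - tau_p Dtil_i) / A_p`, `A_p = mean(Ztil Dtil)`;
#' the split maximising `sum_children (sum_child rho)^2 / n_child` is
#' chosen — the standard computational surrogate for maximising within-leaf
#' treatment-effect heterogeneity. Leaf effect estimates come from the
#' estimation half via the covariance ratio (honesty).
#'
#' @param ds A [trial_dataset()].
#' @param nu Nuisance estimates from [estimate_nuisances()].
#' @param params A [forest_params()].
#' @return An `iv_forest_model`.
#' @export
iv_forest <- function(ds, nu, params = forest_params()) {
  stopifnot(inherits(ds, "trial_dataset"))
  res <- residualise(ds, nu)
  X <- ds$X
  params <- resolve_params(params, ncol(X), ds$n, "instrumental")
  if (abs(mean(res$ztil * res$dtil)) < 1e-10)
    stopf("weak instrument: the root moment mean(Ztil * Dtil) is degenerate")
  R <- cbind(res$ytil, res$dtil, res$ztil)
  trees <- cpp_grow_forest(X, R, 1L, unclass(params))
  forest <- new_forest(trees, params, "instrumental", X, R)
  structure(
    list(forest = forest, residuals = res, nu = nu, params = params,
         feature_names = colnames(X), n = ds$n,
         global_tau = as.numeric(leaf_wald(res$ytil, res$dtil, res$ztil))),
    class = "iv_forest_model")
}

#' @export
print.iv_forest_model <- function(x, ...) {
  cat(sprintf("instrumental forest: %d trees, %d units, %d covariates\n",
              x$params$num_trees, x$n, length(x$feature_names)))
  cat(sprintf("  global residualised Wald estimate: %.4f\n", x$global_tau))
  invisible(x)
}

#' Conditional LATE predictions from an instrumental forest
#'
#' Solves the similarity-weighted moment condition at each target profile:
#' the weighted covariance ratio of (Ytil, Ztil) to (Dtil, Ztil), with
#' weights implied by leaf co-membership in the estimation halves. For
#' training units only out-of-bag trees contribute. A degenerate weighted
#' denominator falls back to the global residualised Wald estimate and is
#' flagged. A forest in which no tree places any split carries no
#' covariate information: its weights are uniform by convention and every
#' prediction equals the global Wald estimate exactly.
#'
#' @param model An `iv_forest_model`.
#' @param newdata Optional matrix of new covariate profiles; default is
#'   out-of-bag prediction for the training units.
#' @return A `clates` data frame: `id`, `tau_hat`, `oob`, `fallback`, with
#'   a `summary` attribute (mean, SD, quantiles) for histogram reporting.
#' @export
predict_clate <- function(model, newdata = NULL) {
  stopifnot(inherits(model, "iv_forest_model"))
  oob <- is.null(newdata)
  if (all_single_leaf(model$forest$trees)) {
    m <- if (oob) model$n else nrow(as_feature_matrix(newdata))
    return(new_clates(rep(model$global_tau, m), oob = oob,
                      fallback = rep(TRUE, m)))
  }
  if (oob) {
    acc <- oob_moments(model$forest)
  } else {
    newdata <- check_schema(model$feature_names, newdata)
    acc <- oob_moments(model$forest, newdata)
  }
  s <- acc$stats
  num <- s[, 4] - s[, 1] * s[, 3]
  den <- s[, 5] - s[, 2] * s[, 3]
  bad <- acc$count == 0 | abs(den) < 1e-10
  tau <- ifelse(bad, model$global_tau, num / den)
  new_clates(tau, oob = oob, fallback = bad)
}

new_clates <- function(tau, oob, fallback) {
  out <- data.frame(id = seq_along(tau), tau_hat = tau,
                    oob = oob, fallback = fallback)
  attr(out, "summary") <- c(mean = mean(tau), sd = sd(tau),
                            quantile(tau, c(0.05, 0.25, 0.5, 0.75, 0.95)))
  class(out) <- c("clates", "data.frame")
  out
}

#' Tune instrumental-forest hyperparameters on an out-of-bag moment loss
#'
#' Fits one forest per grid point and scores it by the mean squared
#' empirical moment violation
#' `mean(((Ytil - tau_oob(X) Dtil) Ztil)^2)` — an R-loss style proxy for
#' CLATE accuracy that needs no ground truth. Ties break toward smaller
#' `mtry`, then larger `min_node_size`.
#'
#' @param ds A [trial_dataset()].
#' @param nu Nuisance estimates.
#' @param grid Data frame whose columns are a subset of
#'   `mtry`, `sample_fraction`, `honesty_fraction`, `alpha`,
#'   `min_node_size`; one row per candidate.
#' @param params Base [forest_params()] supplying unlisted values.
#' @return List with `best` (a `forest_params`), `best_index`, and a
#'   `log` data frame with every candidate's score.
#' @export
tune_iv_forest <- function(ds, nu, grid, params = forest_params()) {
  if (is.null(grid) || nrow(grid) == 0) stopf("tune_iv_forest: empty grid")
  res <- residualise(ds, nu)
  scores <- rep(NA_real_, nrow(grid))
  cand <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- params
    for (f in intersect(names(grid),
                        c("mtry", "sample_fraction", "honesty_fraction",
                          "alpha", "min_node_size", "num_trees"))) {
      v <- grid[[f]][i]
      p[[f]] <- if (f %in% c("mtry", "min_node_size", "num_trees"))
        as.integer(v) else v
    }
    p <- resolve_params(p, ncol(ds$X), ds$n, "instrumental")
    cand[[i]] <- p
    fit <- try(iv_forest(ds, nu, p), silent = TRUE)
    if (inherits(fit, "try-error")) next
    cl <- predict_clate(fit)
    scores[i] <- mean(((res$ytil - cl$tau_hat * res$dtil) * res$ztil)^2)
  }
  if (all(is.na(scores))) stopf("tune_iv_forest: all grid points degenerate")
  log <- cbind(grid,
               mtry_eff = vapply(cand, function(p) p$mtry, 1L),
               min_node_eff = vapply(cand, function(p) p$min_node_size, 1L),
               score = scores)
  ord <- order(scores, log$mtry_eff, -log$min_node_eff)
  best <- ord[1]
  list(best = cand[[best]], best_index = best, log = log)
}
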