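#' Compliance scores via an auxiliary causal forest
#'
#' Estimates the conditional first stage
#' `delta(x) = E(D | X = x, Z = 1) - E(D | X = x, Z = 0)` — the local
#' complier share — with the instrumental-forest machinery applied to D as
#' the outcome and Z serving as both treatment and instrument (a causal
#' forest is the self-instrumented special case). Out-of-bag per-unit
#' estimates are floor-clipped at 0.01; raw negative values are recorded
#' as a monotonicity concern.
#'
#' @param ds A [trial_dataset()].
#' @param params A [forest_params()].
#' @return A `compliance_scores` object with `delta_hat`, the unclipped
#'   `raw` values, clipped-unit indices, and the auxiliary model.
#' @export
compliance_score <- function(ds, params = forest_params()) {
  stopifnot(inherits(ds, "trial_dataset"))
  if (!any(ds$z == 1) || !any(ds$z == 0))
    stopf("compliance_score: both assignment arms required")
  fs <- mean(ds$d[ds$z == 1]) - mean(ds$d[ds$z == 0])
  if (!is.finite(fs) || fs < 1e-3)
    stopf("compliance_score: first stage is degenerate (no compliers)")

  pseed <- function(k) { p <- params; p$seed <- as.integer(sub_seed(params$seed, k)); p }
  mD_forest <- regression_forest(ds$X, ds$d, pseed(21))
  g_forest <- regression_forest(ds$X, ds$z, pseed(22))
  mD <- predict_oob(mD_forest)
  g <- clip01(predict_oob(g_forest))
  ztil <- ds$z - g
  R <- cbind(ds$d - mD, ztil, ztil)
  p <- resolve_params(pseed(23), ncol(ds$X), ds$n, "instrumental")
  trees <- cpp_grow_forest(ds$X, R, 1L, unclass(p))
  forest <- new_forest(trees, p, "instrumental", ds$X, R)
  model <- structure(
    list(forest = forest,
         residuals = list(ytil = R[, 1], dtil = R[, 2], ztil = R[, 3]),
         nu = NULL, params = p, feature_names = colnames(ds$X), n = ds$n,
         global_tau = as.numeric(leaf_wald(R[, 1], R[, 2], R[, 3]))),
    class = "iv_forest_model")
  raw <- predict_clate(model)$tau_hat
  structure(
    list(delta_hat = pmax(raw, 0.01), raw = raw,
         clipped = which(raw < 0.01), n_negative = sum(raw < 0),
         model = model),
    class = "compliance_scores")
}

#' Doubly robust (AIPW) scores for the LATE
#'
#' Per-unit scores
#' `Gamma_i = tau_hat(X_i) +
#'   ((Z_i - g_hat_i) / (g_hat_i (1 - g_hat_i))) / delta_hat_i *
#'   ((Y_i - m_hat_i) - (D_i - e_hat_i) tau_hat(X_i))`,
#' whose mean estimates the LATE and is consistent if either the outcome
#' model or the propensity/instrument models are correct. The correction
#' residual is `(Y - m_hat) - (D - e_hat) tau_hat` — each factor is
#' mean-zero given X, which is what makes the augmentation unbiased.
#'
#' @param ds A [trial_dataset()].
#' @param clates CLATE predictions (OOB) from [predict_clate()].
#' @param nu Nuisance estimates from [estimate_nuisances()].
#' @param cs Compliance scores from [compliance_score()].
#' @return A `dr_scores` data frame: `id`, `gamma`, `delta_clipped`.
#' @export
dr_score <- function(ds, clates, nu, cs) {
  stopifnot(inherits(ds, "trial_dataset"), inherits(cs, "compliance_scores"))
  tau <- if (is.data.frame(clates)) clates$tau_hat else as.numeric(clates)
  if (length(tau) != ds$n || length(cs$delta_hat) != ds$n ||
      length(nu$m_hat) != ds$n)
    stopf("dr_score: inputs are not aligned with the dataset")
  w <- (ds$z - nu$g_hat) / (nu$g_hat * (1 - nu$g_hat))
  resid <- (ds$y - nu$m_hat) - (ds$d - nu$e_hat) * tau
  gamma <- tau + (w / cs$delta_hat) * resid
  out <- data.frame(id = seq_len(ds$n), gamma = gamma,
                    delta_clipped = seq_len(ds$n) %in% cs$clipped)
  class(out) <- c("dr_scores", "data.frame")
  out
}

#' Local average treatment effect from doubly robust scores
#'
#' The point estimate is the mean of the scores; the standard error is the
#' i.i.d. formula `sd(Gamma) / sqrt(N)`; the 95% interval is
#' `estimate +/- 1.96 se`.
#'
#' @param scores A `dr_scores` object or a plain numeric vector of scores.
#' @return A `late_estimate` with `tau_hat`, `se`, `ci95`, `n` and a
#'   method tag.
#' @export
late <- function(scores) {
  g <- if (is.data.frame(scores)) scores$gamma else as.numeric(scores)
  n <- length(g)
  if (n < 2) stopf("late: need at least 2 scores")
  est <- mean(g)
  se <- sd(g) / sqrt(n)
  new_late(est, se, n, "aipw_forest")
}

new_late <- function(est, se, n, method) {
  structure(list(tau_hat = est, se = se,
                 ci95 = c(est - 1.96 * se, est + 1.96 * se),
                 n = n, method = method),
            class = "late_estimate")
}

#' @export
print.late_estimate <- function(x, ...) {
  cat(sprintf("LATE (%s): %.4f (SE = %.4f), 95%% CI [%.4f, %.4f], n = %d\n",
              x$method, x$tau_hat, x$se, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' Conventional two-stage least squares baseline
#'
#' Linear 2SLS of Y on D instrumented by Z, with optional linear covariate
#' adjustment. With no covariates the point estimate equals the
#' unconditional Wald ratio exactly. Standard errors use the conventional
#' IV sandwich with homoskedastic residuals by default; set
#' `robust = TRUE` for the heteroskedasticity-robust version.
#'
#' @param ds A [trial_dataset()].
#' @param covariates Optional character vector of covariate columns to
#'   adjust for linearly.
#' @param robust Heteroskedasticity-robust standard errors.
#' @return A `late_estimate` with method tag `"tsls"`.
#' @export
baseline_2sls <- function(ds, covariates = NULL, robust = FALSE) {
  stopifnot(inherits(ds, "trial_dataset"))
  n <- ds$n
  Xc <- if (is.null(covariates)) NULL else {
    miss <- setdiff(covariates, colnames(ds$X))
    if (length(miss)) stopf("baseline_2sls: unknown covariates: %s",
                            paste(miss, collapse = ", "))
    ds$X[, covariates, drop = FALSE]
  }
  W <- cbind(`(Intercept)` = 1, d = ds$d, Xc)
  Zm <- cbind(`(Intercept)` = 1, z = ds$z, Xc)
  for (M in list(W = W, Zm = Zm)) {
    qd <- qr(M)
    if (qd$rank < ncol(M))
      stopf("baseline_2sls: rank-deficient design; collinear column(s): %s",
            paste(colnames(M)[qd$pivot[(qd$rank + 1):ncol(M)]], collapse = ", "))
  }
  fs <- mean(ds$d[ds$z == 1]) - mean(ds$d[ds$z == 0])
  if (abs(fs) < 1e-10) stopf("baseline_2sls: instrument has no first stage")

  # two-stage algebra: project the endogenous column on the instruments
  Dhat <- Zm %*% qr.solve(crossprod(Zm), crossprod(Zm, ds$d))
  What <- cbind(`(Intercept)` = 1, d = as.vector(Dhat), Xc)
  XtX <- crossprod(What)
  beta <- qr.solve(XtX, crossprod(What, ds$y))
  u <- ds$y - as.vector(W %*% beta)     # residuals use the actual D
  k <- ncol(W)
  bread <- solve(XtX)
  V <- if (robust) {
    meat <- crossprod(What * u)
    (n / (n - k)) * bread %*% meat %*% bread
  } else {
    sum(u^2) / (n - k) * bread
  }
  new_late(as.numeric(beta[2]), sqrt(V[2, 2]), n, "tsls")
}
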