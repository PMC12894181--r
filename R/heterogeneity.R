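#' Best linear predictors of treatment-effect heterogeneity
#'
#' Ordinary least squares of the doubly robust scores on the covariates.
#' Coefficients are partial associations with the conditional effect
#' conditional on a linear index of the other columns — never causal
#' effects. One reference level per indicator family (e.g. the third
#' tercile) should be dropped via `reference` to keep the design full
#' rank. Standard errors are heteroskedasticity-robust (HC1 sandwich) by
#' default, since the scores are heteroskedastic by construction; set
#' `robust = FALSE` for classical OLS standard errors.
#'
#' @param gamma A `dr_scores` object or numeric score vector.
#' @param X Covariate matrix of 0/1 indicators.
#' @param reference Character vector of reference-category columns to drop.
#' @param robust Use sandwich standard errors.
#' @return A `blp_result` data frame: term, estimate, se, ci, p-value.
#' @export
blp <- function(gamma, X, reference = NULL, robust = TRUE) {
  g <- if (is.data.frame(gamma)) gamma$gamma else as.numeric(gamma)
  X <- as_feature_matrix(X)
  if (length(g) != nrow(X)) stopf("blp: gamma and X are not aligned")
  if (!is.null(reference)) {
    miss <- setdiff(reference, colnames(X))
    if (length(miss)) stopf("blp: unknown reference column(s): %s",
                            paste(miss, collapse = ", "))
    X <- X[, setdiff(colnames(X), reference), drop = FALSE]
  }
  M <- cbind(`(Intercept)` = 1, X)
  qd <- qr(M)
  if (qd$rank < ncol(M))
    stopf("blp: collinear design; offending column(s): %s",
          paste(colnames(M)[qd$pivot[(qd$rank + 1):ncol(M)]], collapse = ", "))
  df <- data.frame(gamma = g, X, check.names = FALSE)
  fit <- lm(gamma ~ ., data = df)
  V <- if (robust) sandwich::vcovHC(fit, type = "HC1") else vcov(fit)
  est <- coef(fit)
  se <- sqrt(diag(V))
  out <- data.frame(term = names(est), estimate = unname(est),
                    se = unname(se),
                    ci_lo = unname(est - 1.96 * se),
                    ci_hi = unname(est + 1.96 * se),
                    p_value = unname(2 * pnorm(-abs(est / se))),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "robust") <- robust
  class(out) <- c("blp_result", "data.frame")
  out
}

#' Default reference categories for tercile indicator families
#'
#' For every family of columns `stem_q1`, `stem_q2`, `stem_q3` present in
#' the schema, the third tercile is designated the reference level (to be
#' dropped from a regression design).
#'
#' @param columns Character vector of covariate names.
#' @return Character vector of reference columns (possibly empty).
#' @export
default_reference <- function(columns) {
  stems <- unique(sub("_q[123]$", "", grep("_q[123]$", columns, value = TRUE)))
  refs <- paste0(stems, "_q3")
  refs[vapply(stems, function(s) all(paste0(s, "_q", 1:3) %in% columns),
              logical(1))]
}

#' Classification analysis (CLAN) of the most and least affected groups
#'
#' Ranks units by their doubly robust scores (ties broken by stable input
#' order), splits them into `n_groups` equal groups, and for every
#' covariate compares its mean in the most-affected group against the
#' least-affected group with a two-sample standard error. This is a
#' univariate analysis: modifiers are examined one at a time, without
#' adjusting for the others.
#'
#' @param gamma A `dr_scores` object or numeric score vector.
#' @param X Covariate matrix.
#' @param n_groups Number of ranked groups (default quartiles).
#' @param rank_scores Optional alternative ranking variable (e.g. CLATEs
#'   instead of scores) for sensitivity analysis; default ranks by `gamma`.
#' @return A `clan_result` data frame with per-covariate group means,
#'   difference, SE, 95% CI, p-value and a degenerate-SE flag.
#' @export
clan <- function(gamma, X, n_groups = 4, rank_scores = NULL) {
  g <- if (is.data.frame(gamma)) gamma$gamma else as.numeric(gamma)
  X <- as_feature_matrix(X)
  n <- length(g)
  if (n < 2 * n_groups) stopf("clan: need at least 2 units per group")
  r <- if (is.null(rank_scores)) g else as.numeric(rank_scores)
  ord <- order(-r) # stable: ties keep input order
  sizes <- rep(n %/% n_groups, n_groups)
  sizes[seq_len(n %% n_groups)] <- sizes[seq_len(n %% n_groups)] + 1
  grp <- integer(n)
  grp[ord] <- rep(seq_len(n_groups), times = sizes)
  top <- grp == 1
  bottom <- grp == n_groups

  res <- lapply(colnames(X), function(cn) {
    v <- X[, cn]
    m1 <- mean(v[top]); m4 <- mean(v[bottom])
    v1 <- var(v[top]); v4 <- var(v[bottom])
    se <- sqrt(v1 / sum(top) + v4 / sum(bottom))
    degenerate <- !is.finite(se) || se == 0
    dd <- m1 - m4
    data.frame(variable = cn, mean_most = m1, mean_least = m4,
               difference = dd, se = se,
               ci_lo = dd - 1.96 * se, ci_hi = dd + 1.96 * se,
               p_value = if (degenerate) NA_real_ else 2 * pnorm(-abs(dd / se)),
               degenerate_se = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "group_sizes") <- sizes
  class(out) <- c("clan_result", "data.frame")
  out
}

#' Variable importance from instrumental-forest split frequencies
#'
#' Importance of covariate k is the depth-weighted split frequency
#' `sum_{d <= max_depth} (share of depth-d splits using k) * d^(-decay)`,
#' normalised to sum to 1 across covariates. Only the relative ranking is
#' meaningful. `mode = "variance"` instead weights each split by the
#' heterogeneity-criterion gain it produced.
#'
#' @param model An `iv_forest_model` (or any `honest_forest`).
#' @param max_depth Deepest split level counted.
#' @param decay Depth-decay exponent.
#' @param mode `"frequency"` (default) or `"variance"`.
#' @return A `vi_ranking` data frame sorted by decreasing importance.
#' @export
variable_importance <- function(model, max_depth = 4, decay = 2,
                                mode = c("frequency", "variance")) {
  mode <- match.arg(mode)
  forest <- if (inherits(model, "iv_forest_model")) model$forest else model
  stopifnot(inherits(forest, "honest_forest"))
  if (length(forest$trees) == 0) stopf("variable_importance: empty forest")
  p <- length(forest$feature_names)
  splits <- do.call(rbind, lapply(forest$trees, function(tr) {
    keep <- !is.na(tr$var)
    cbind(var = tr$var[keep], depth = tr$depth[keep], gain = tr$gain[keep])
  }))
  imp <- numeric(p)
  if (!is.null(splits) && nrow(splits) > 0) {
    splits <- splits[splits[, "depth"] <= max_depth, , drop = FALSE]
    if (mode == "frequency") {
      for (d in unique(splits[, "depth"])) {
        sel <- splits[, "depth"] == d
        cnt <- tabulate(splits[sel, "var"], nbins = p)
        imp <- imp + (cnt / sum(cnt)) * d^(-decay)
      }
    } else {
      for (j in seq_len(p))
        imp[j] <- sum(splits[splits[, "var"] == j, "gain"])
    }
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  out <- data.frame(variable = forest$feature_names, importance = imp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  class(out) <- c("vi_ranking", "data.frame")
  out
}

#' Top rows of a variable-importance ranking
#'
#' @param vi A `vi_ranking`.
#' @param k Number of rows.
#' @return The first `k` rows.
#' @export
vi_top <- function(vi, k = 10) {
  utils::head(as.data.frame(vi), k)
}
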