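#' Construct a trial dataset
#'
#' The common container for every stage of the pipeline: a binary outcome
#' `y`, the treatment actually received `d`, the randomised assignment
#' (instrument) `z`, and a matrix of covariates. Covariate columns that
#' describe local service supply (health-worker availability terciles,
#' village concern indicators) can be tagged so that the treatment
#' propensity model can exclude them, mirroring designs where supply-side
#' readiness determined eligibility.
#'
#' @param y Outcome vector. Binary in the main analysis; set
#'   `allow_nonbinary_y = TRUE` for aggregated/grouped fixtures or
#'   continuous outcomes.
#' @param d Treatment received, strictly 0/1.
#' @param z Randomised assignment, strictly 0/1.
#' @param X Covariate matrix or data frame with named columns.
#' @param cluster Optional assignment-cluster labels (one per unit).
#' @param supply_tags Character vector naming the supply-side columns of `X`.
#' @param allow_nonbinary_y Permit a non-binary outcome.
#' @return An object of class `trial_dataset` with elements `y`, `d`, `z`,
#'   `X`, `cluster`, `supply_tags` and `n`.
#' @export
trial_dataset <- function(y, d, z, X, cluster = NULL,
                          supply_tags = character(),
                          allow_nonbinary_y = FALSE) {
  X <- as_feature_matrix(X)
  n <- length(y)
  if (n < 1) stopf("trial_dataset: empty dataset")
  if (length(d) != n || length(z) != n || nrow(X) != n)
    stopf("trial_dataset: y, d, z and X must have the same number of units")
  if (anyNA(y) || anyNA(d) || anyNA(z) || anyNA(X))
    stopf("trial_dataset: missing values are not allowed (complete cases only)")
  if (!is_binary(d)) stopf("trial_dataset: d must be strictly 0/1")
  if (!is_binary(z)) stopf("trial_dataset: z must be strictly 0/1")
  if (!allow_nonbinary_y && !is_binary(y))
    stopf("trial_dataset: y must be strictly 0/1 (or set allow_nonbinary_y)")
  if (length(supply_tags) && !all(supply_tags %in% colnames(X)))
    stopf("trial_dataset: supply_tags not in X: %s",
          paste(setdiff(supply_tags, colnames(X)), collapse = ", "))
  if (!is.null(cluster) && length(cluster) != n)
    stopf("trial_dataset: cluster labels must have one entry per unit")
  structure(
    list(y = as.numeric(y), d = as.integer(d), z = as.integer(z), X = X,
         cluster = cluster, supply_tags = supply_tags, n = n),
    class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("trial_dataset: %d units, %d covariates (%d supply-tagged)\n",
              x$n, ncol(x$X), length(x$supply_tags)))
  cat(sprintf("  mean(y)=%.3f  P(D=1)=%.3f  P(Z=1)=%.3f\n",
              mean(x$y), mean(x$d), mean(x$z)))
  invisible(x)
}

#' Build a treatment-by-assignment contingency table from counts
#'
#' @param not_enrolled_control,enrolled_control Counts with Z = 0.
#' @param not_enrolled_treated,enrolled_treated Counts with Z = 1.
#' @return A `crosstab`: a 2x2 count matrix (rows D = 0/1, columns Z = 0/1)
#'   with whole-percent within-column shares attached.
#' @export
crosstab <- function(not_enrolled_control, enrolled_control,
                     not_enrolled_treated, enrolled_treated) {
  cnt <- matrix(c(not_enrolled_control, enrolled_control,
                  not_enrolled_treated, enrolled_treated),
                nrow = 2, ncol = 2,
                dimnames = list(D = c("not_enrolled", "enrolled"),
                                Z = c("control", "treated")))
  if (any(cnt < 0)) stopf("crosstab: counts must be non-negative")
  pct <- round(100 * sweep(cnt, 2, colSums(cnt), "/"))
  structure(cnt, percent = pct, class = c("crosstab", "matrix"))
}

#' Contingency table of treatment received by randomised assignment
#'
#' Counts units in the four (D, Z) cells and reports within-assignment-arm
#' percentages rounded to whole percents.
#'
#' @param ds A [trial_dataset()].
#' @return A `crosstab` object.
#' @export
contingency <- function(ds) {
  stopifnot(inherits(ds, "trial_dataset"))
  crosstab(sum(ds$d == 0 & ds$z == 0), sum(ds$d == 1 & ds$z == 0),
           sum(ds$d == 0 & ds$z == 1), sum(ds$d == 1 & ds$z == 1))
}

#' @export
print.crosstab <- function(x, ...) {
  cnt <- unclass(x)
  attr(cnt, "percent") <- NULL
  pct <- attr(x, "percent")
  cat("enrolment (D) by assignment (Z):\n")
  for (i in 1:2) {
    cat(sprintf("  %-13s %6d (%d%%) %6d (%d%%)\n", rownames(cnt)[i],
                cnt[i, 1], pct[i, 1], cnt[i, 2], pct[i, 2]))
  }
  invisible(x)
}

#' Principal-strata shares from a contingency table
#'
#' Under monotonicity (no defiers), the always-taker share is
#' P(D=1 | Z=0), the never-taker share is P(D=0 | Z=1), and compliers make
#' up the remainder. Two reporting conventions are supported:
#' `"one_decimal_percent"` rounds the always- and never-taker shares to one
#' decimal in percent units and defines the complier share as the
#' complement, so the three printed numbers always sum to 100;
#' `"raw"` returns unrounded proportions with the complier share equal to
#' the first-stage difference P(D=1|Z=1) - P(D=1|Z=0).
#'
#' @param tab A `crosstab`.
#' @param rounding Reporting convention; see Details.
#' @return An object of class `strata_shares` with `p_always`, `p_never`,
#'   `p_complier`, the convention used, and a `monotonicity_violation` flag
#'   set when the raw complier share is negative.
#' @export
strata_shares <- function(tab, rounding = c("one_decimal_percent", "raw")) {
  stopifnot(inherits(tab, "crosstab"))
  rounding <- match.arg(rounding)
  cnt <- unclass(tab)
  n0 <- sum(cnt[, "control"])
  n1 <- sum(cnt[, "treated"])
  if (n0 == 0 || n1 == 0) stopf("strata_shares: empty assignment stratum")
  pa <- cnt["enrolled", "control"] / n0
  pn <- cnt["not_enrolled", "treated"] / n1
  pc_raw <- cnt["enrolled", "treated"] / n1 - pa
  violation <- pc_raw < 0
  if (violation)
    warning("negative raw complier share: monotonicity violated", call. = FALSE)
  if (rounding == "one_decimal_percent") {
    pa_r <- round(100 * pa, 1)
    pn_r <- round(100 * pn, 1)
    out <- list(p_always = pa_r, p_never = pn_r,
                p_complier = 100 - pa_r - pn_r)
  } else {
    out <- list(p_always = pa, p_never = pn, p_complier = pc_raw)
  }
  out$rounding <- rounding
  out$monotonicity_violation <- violation
  structure(out, class = "strata_shares")
}

#' @export
print.strata_shares <- function(x, ...) {
  unit <- if (x$rounding == "one_decimal_percent") "%" else ""
  cat(sprintf("compliers %s%s, always-takers %s%s, never-takers %s%s\n",
              format(x$p_complier), unit, format(x$p_always), unit,
              format(x$p_never), unit))
  invisible(x)
}

#' Standardised mean differences between randomised or enrolment groups
#'
#' Balance diagnostic: for the outcome and every covariate,
#' (mean in group 1 - mean in group 0) / pooled SD, with pooled SD
#' `sqrt((s0^2 + s1^2) / 2)` (sample variances). Columns with zero pooled
#' SD return an SMD of 0 when the group means agree and are flagged
#' otherwise.
#'
#' @param ds A [trial_dataset()].
#' @param group Grouping column, `"z"` (assignment) or `"d"` (enrolment).
#' @return Data frame with per-column group means, `smd`, and a
#'   `zero_variance` flag.
#' @export
smd <- function(ds, group = c("z", "d")) {
  stopifnot(inherits(ds, "trial_dataset"))
  group <- match.arg(group)
  g <- if (group == "z") ds$z else ds$d
  if (length(unique(g)) < 2) stopf("smd: both groups must be non-empty")
  M <- cbind(y = ds$y, ds$X)
  res <- lapply(colnames(M), function(cn) {
    v <- M[, cn]
    m0 <- mean(v[g == 0]); m1 <- mean(v[g == 1])
    s2 <- (var(v[g == 0]) + var(v[g == 1])) / 2
    if (s2 <= 0) {
      data.frame(variable = cn, mean0 = m0, mean1 = m1,
                 smd = 0, zero_variance = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(variable = cn, mean0 = m0, mean1 = m1,
                 smd = (m1 - m0) / sqrt(s2), zero_variance = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  # a zero-variance column with differing means cannot be standardised
  bad <- out$zero_variance & abs(out$mean1 - out$mean0) > 0
  out$smd[bad] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Tercile indicator encoding of a numeric column
#'
#' Discretises a continuous column into three indicator columns using the
#' inclusive empirical quantile (type 1) at 1/3 and 2/3. Ties are assigned
#' to the lower tercile, so every unit falls in exactly one indicator.
#'
#' @param v Numeric vector, length at least 3, not constant.
#' @param name Stem for the indicator column names (`name_q1..q3`).
#' @return An n-by-3 0/1 matrix whose rows sum to 1.
#' @export
tercile_encode <- function(v, name = "x") {
  if (length(v) < 3) stopf("tercile_encode: need at least 3 values")
  if (length(unique(v)) < 2) stopf("tercile_encode: constant column has no terciles")
  q <- quantile(v, c(1 / 3, 2 / 3), type = 1, names = FALSE)
  out <- cbind(as.numeric(v <= q[1]),
               as.numeric(v > q[1] & v <= q[2]),
               as.numeric(v > q[2]))
  colnames(out) <- paste0(name, "_q", 1:3)
  out
}
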