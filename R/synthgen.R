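#' Configure a synthetic encouragement-design trial
#'
#' Defines a data-generating process with known ground truth for a
#' cluster-randomised encouragement design with one-sided and two-sided
#' non-compliance: units belong to principal strata (complier,
#' always-taker, never-taker), assignment Z is Bernoulli, treatment
#' received D follows the monotonicity rule, and binary potential outcomes
#' are drawn from a clipped linear probability model
#' `P(Y(d) = 1) = clip(m(x) + tau(x) d, 0.01, 0.99)`.
#'
#' A single integer seed drives four independent sub-streams (covariates,
#' strata, assignment, noise), so e.g. re-drawing the assignment leaves the
#' potential outcomes bit-identical — the exclusion restriction holds by
#' construction.
#'
#' @param n Number of units.
#' @param p_assign Probability of assignment Z = 1, in (0, 1).
#' @param strata_probs Named or positional triple
#'   (complier, always, never), non-negative, summing to 1.
#' @param covariates Named list of covariate specs; each element is either
#'   `list(kind = "binary", prob = p)` or `list(kind = "tercile")` (a latent
#'   uniform discretised into `name_q1..q3` indicators).
#' @param tau Effect function: `list(intercept = t0, coef = c(name = g, ...))`
#'   in risk-difference units. Coefficient names must reference expanded
#'   covariate columns.
#' @param baseline Baseline function m(x), same structure as `tau`.
#' @param noise_sd If `NULL` (default) outcomes are binary; a numeric value
#'   switches to continuous outcomes `Y(d) = m(x) + tau(x) d + eps` with
#'   `eps ~ N(0, noise_sd)`.
#' @param n_clusters Optional number of assignment clusters; Z is constant
#'   within cluster when set.
#' @param supply_tags Expanded column names to tag as supply-side.
#' @param strata_covariate,strata_coef Optional logistic tilt of the
#'   complier probability on one expanded covariate column, for
#'   complier-composition experiments. Default: strata independent of X.
#' @param seed Integer seed; fully determines the generated dataset.
#' @return A `synth_config`.
#' @export
synth_config <- function(n, p_assign = 0.5,
                         strata_probs = c(complier = 1, always = 0, never = 0),
                         covariates = list(x1 = list(kind = "binary", prob = 0.5)),
                         tau = list(intercept = 0.2, coef = numeric()),
                         baseline = list(intercept = 0.4, coef = numeric()),
                         noise_sd = NULL, n_clusters = NULL,
                         supply_tags = character(),
                         strata_covariate = NULL, strata_coef = 0,
                         seed = 1) {
  if (n < 1) stopf("synth_config: n must be positive")
  if (p_assign <= 0 || p_assign >= 1) stopf("synth_config: p_assign must be in (0,1)")
  strata_probs <- unname(strata_probs)
  if (length(strata_probs) != 3 || any(strata_probs < 0) ||
      abs(sum(strata_probs) - 1) > 1e-12)
    stopf("synth_config: strata_probs must be a non-negative triple summing to 1")
  kinds <- vapply(covariates, function(s) s$kind, "")
  if (!all(kinds %in% c("binary", "tercile")))
    stopf("synth_config: covariate kind must be 'binary' or 'tercile'")
  cols <- expanded_names(covariates)
  for (spec_name in c("tau", "baseline")) {
    cf <- get(spec_name)$coef
    if (length(cf) && !all(names(cf) %in% cols))
      stopf("synth_config: %s references undeclared covariate(s): %s",
            spec_name, paste(setdiff(names(cf), cols), collapse = ", "))
  }
  if (length(supply_tags) && !all(supply_tags %in% cols))
    stopf("synth_config: supply_tags reference undeclared columns")
  if (!is.null(strata_covariate) && !strata_covariate %in% cols)
    stopf("synth_config: strata_covariate not among covariate columns")
  structure(
    list(n = as.integer(n), p_assign = p_assign,
         strata_probs = c(complier = strata_probs[1], always = strata_probs[2],
                          never = strata_probs[3]),
         covariates = covariates, tau = tau, baseline = baseline,
         noise_sd = noise_sd, n_clusters = n_clusters,
         supply_tags = supply_tags, strata_covariate = strata_covariate,
         strata_coef = strata_coef, seed = as.integer(seed)),
    class = "synth_config")
}

expanded_names <- function(covariates) {
  unlist(lapply(names(covariates), function(nm) {
    if (covariates[[nm]]$kind == "binary") nm else paste0(nm, "_q", 1:3)
  }), use.names = FALSE)
}

#' Preset synthetic trial configurations
#'
#' `pkh2009` and `pkh2013` emulate the compliance structure of a large CCT
#' experiment's two follow-up waves: principal-strata shares
#' (complier, always, never) of (0.398, 0.096, 0.506) and
#' (0.344, 0.137, 0.519) respectively, 50/50 assignment, binary utilisation
#' outcomes with baseline rates in the 0.3-0.85 range, and treatment
#' effects that vary with health-worker supply and household amenities.
#' `homogeneous` uses the 2009 strata with a constant effect tau = 0.2
#' (all interaction coefficients zero). `planted_binary` plants a single
#' binary modifier x1 with tau = 0.4 x1 among noise covariates.
#'
#' @param preset One of `"pkh2009"`, `"pkh2013"`, `"homogeneous"`,
#'   `"planted_binary"`.
#' @param n Number of units.
#' @param seed Integer seed.
#' @return A [synth_config()].
#' @export
synth_preset <- function(preset = c("pkh2009", "pkh2013", "homogeneous",
                                    "planted_binary"),
                         n = 4000, seed = 1) {
  preset <- match.arg(preset)
  pkh_covs <- list(
    subsidised_ins = list(kind = "binary", prob = 0.74),
    urban          = list(kind = "binary", prob = 0.12),
    java           = list(kind = "binary", prob = 0.62),
    educated       = list(kind = "binary", prob = 0.81),
    agri           = list(kind = "binary", prob = 0.59),
    no_latrine     = list(kind = "binary", prob = 0.49),
    no_electricity = list(kind = "binary", prob = 0.20),
    doctor         = list(kind = "tercile"),
    nurse          = list(kind = "tercile"),
    midwife        = list(kind = "tercile"),
    concern_facilities = list(kind = "binary", prob = 0.30))
  pkh_tags <- c(paste0("doctor_q", 1:3), paste0("nurse_q", 1:3),
                paste0("midwife_q", 1:3), "concern_facilities")
  pkh_m <- list(intercept = 0.45,
                coef = c(educated = 0.10, urban = 0.08, agri = -0.06,
                         doctor_q3 = 0.06, nurse_q3 = 0.04,
                         no_electricity = -0.05))
  pkh_tau <- function(t0) list(intercept = t0,
                               coef = c(doctor_q3 = 0.07,
                                        no_electricity = -0.05))
  s2009 <- c(0.398, 0.096, 0.506)
  s2013 <- c(0.344, 0.137, 0.519)
  switch(preset,
    pkh2009 = synth_config(n, strata_probs = s2009, covariates = pkh_covs,
                           tau = pkh_tau(0.15), baseline = pkh_m,
                           supply_tags = pkh_tags, seed = seed),
    pkh2013 = synth_config(n, strata_probs = s2013, covariates = pkh_covs,
                           tau = pkh_tau(0.17), baseline = pkh_m,
                           supply_tags = pkh_tags, seed = seed),
    homogeneous = synth_config(n, strata_probs = s2009, covariates = pkh_covs,
                               tau = list(intercept = 0.2, coef = numeric()),
                               baseline = pkh_m, supply_tags = pkh_tags,
                               seed = seed),
    planted_binary = synth_config(
      n, strata_probs = s2009,
      covariates = list(x1 = list(kind = "binary", prob = 0.5),
                        x2 = list(kind = "binary", prob = 0.5),
                        x3 = list(kind = "binary", prob = 0.5),
                        x4 = list(kind = "binary", prob = 0.5),
                        x5 = list(kind = "binary", prob = 0.5)),
      tau = list(intercept = 0, coef = c(x1 = 0.4)),
      baseline = list(intercept = 0.4, coef = c(x2 = 0.05)),
      seed = seed))
}

eval_linear <- function(spec, X) {
  out <- rep(spec$intercept, nrow(X))
  if (length(spec$coef))
    out <- out + as.vector(X[, names(spec$coef), drop = FALSE] %*% spec$coef)
  out
}

#' Read or write a generator configuration as a flat key-value file
#'
#' The file holds one `key = value` pair per line (`#` comments allowed).
#' Documented keys mirror the [synth_config()] fields: `n`, `p_assign`,
#' `strata_probs` (three comma-separated numbers: complier, always,
#' never), `noise_sd`, `n_clusters`, `seed`, `supply_tags`
#' (comma-separated column names), `tau_intercept`, `m_intercept`,
#' covariate declarations `covariate_<name> = binary:<prob>` or
#' `covariate_<name> = tercile`, and coefficient entries
#' `tau_<column> = <value>` / `m_<column> = <value>`. Alternatively a
#' single `preset = <name>` line (plus optional `n`, `seed`) selects a
#' [synth_preset()].
#'
#' @param path File to read.
#' @return A [synth_config()].
#' @export
read_synth_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stopf("read_synth_config: malformed line: '%s'", lines[bad][1])
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  get1 <- function(k, default = NULL) if (k %in% keys) vals[keys == k][1] else default
  nums <- function(s) as.numeric(strsplit(s, ",")[[1]])

  if (!is.null(get1("preset"))) {
    return(synth_preset(get1("preset"),
                        n = as.integer(get1("n", "4000")),
                        seed = as.integer(get1("seed", "1"))))
  }
  covs <- list()
  for (k in keys[startsWith(keys, "covariate_")]) {
    nm <- sub("^covariate_", "", k)
    v <- get1(k)
    covs[[nm]] <- if (v == "tercile") list(kind = "tercile") else {
      if (!startsWith(v, "binary:"))
        stopf("read_synth_config: covariate '%s' must be 'tercile' or 'binary:<prob>'", nm)
      list(kind = "binary", prob = as.numeric(sub("^binary:", "", v)))
    }
  }
  if (length(covs) == 0) covs <- list(x1 = list(kind = "binary", prob = 0.5))
  coef_of <- function(prefix) {
    ks <- keys[startsWith(keys, prefix) & keys != paste0(prefix, "intercept")]
    stats::setNames(as.numeric(vals[match(ks, keys)]), sub(prefix, "", ks))
  }
  synth_config(
    n = as.integer(get1("n", "1000")),
    p_assign = as.numeric(get1("p_assign", "0.5")),
    strata_probs = nums(get1("strata_probs", "1,0,0")),
    covariates = covs,
    tau = list(intercept = as.numeric(get1("tau_intercept", "0.2")),
               coef = coef_of("tau_")),
    baseline = list(intercept = as.numeric(get1("m_intercept", "0.4")),
                    coef = coef_of("m_")),
    noise_sd = if (is.null(get1("noise_sd"))) NULL else as.numeric(get1("noise_sd")),
    n_clusters = if (is.null(get1("n_clusters"))) NULL else as.integer(get1("n_clusters")),
    supply_tags = if (is.null(get1("supply_tags"))) character()
                  else trimws(strsplit(get1("supply_tags"), ",")[[1]]),
    seed = as.integer(get1("seed", "1")))
}

#' Generate a synthetic trial with ground truth
#'
#' Draws covariates, principal strata, assignment and potential outcomes
#' according to a [synth_config()]. Treatment received is determined by the
#' monotonicity rule (`D = 1` iff always-taker, or complier with `Z = 1`);
#' potential outcomes never reference Z, so the exclusion restriction holds
#' by construction. The same seed always yields the same dataset.
#'
#' @param config A [synth_config()].
#' @return A `synth_dataset`: a list with `data` (a [trial_dataset()]) and
#'   `truth` (per-unit stratum, true tau(x), true m(x) and both potential
#'   outcomes).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n

  # stream 1: covariates
  set.seed(sub_seed(config$seed, 1))
  cols <- list()
  for (nm in names(config$covariates)) {
    spec <- config$covariates[[nm]]
    if (spec$kind == "binary") {
      cols[[nm]] <- rbinom(n, 1, spec$prob)
    } else {
      latent <- runif(n)
      terc <- tercile_encode(latent, name = nm)
      for (cc in colnames(terc)) cols[[cc]] <- terc[, cc]
    }
  }
  X <- as_feature_matrix(as.data.frame(cols))

  # stream 2: principal strata
  set.seed(sub_seed(config$seed, 2))
  pr <- config$strata_probs
  if (!is.null(config$strata_covariate) && config$strata_coef != 0) {
    xsel <- X[, config$strata_covariate]
    pc <- plogis(qlogis(pr["complier"]) + config$strata_coef * xsel)
    rest <- 1 - pc
    base_rest <- pr["always"] + pr["never"]
    pa <- if (base_rest > 0) rest * pr["always"] / base_rest else rest * 0
    pn <- rest - pa
    u <- runif(n)
    stratum <- ifelse(u < pc, "complier", ifelse(u < pc + pa, "always", "never"))
  } else {
    u <- runif(n)
    stratum <- ifelse(u < pr["complier"], "complier",
                      ifelse(u < pr["complier"] + pr["always"], "always", "never"))
  }

  # stream 3: assignment
  set.seed(sub_seed(config$seed, 3))
  if (!is.null(config$n_clusters)) {
    cluster <- rep_len(seq_len(config$n_clusters), n)
    zc <- rbinom(config$n_clusters, 1, config$p_assign)
    z <- zc[cluster]
  } else {
    cluster <- NULL
    z <- rbinom(n, 1, config$p_assign)
  }

  d <- as.integer(stratum == "always" | (stratum == "complier" & z == 1))

  # stream 4: outcome noise
  set.seed(sub_seed(config$seed, 4))
  m_x <- eval_linear(config$baseline, X)
  t_x <- eval_linear(config$tau, X)
  if (is.null(config$noise_sd)) {
    p0 <- clip01(m_x)
    p1 <- clip01(m_x + t_x)
    u <- runif(n)
    y0 <- as.numeric(u < p0)
    y1 <- as.numeric(u < p1)
    true_tau <- p1 - p0
    binary <- TRUE
  } else {
    eps <- rnorm(n, 0, config$noise_sd)
    y0 <- m_x + eps
    y1 <- m_x + t_x + eps
    true_tau <- t_x
    binary <- FALSE
  }
  y <- ifelse(d == 1, y1, y0)

  data <- trial_dataset(y, d, z, X, cluster = cluster,
                        supply_tags = config$supply_tags,
                        allow_nonbinary_y = !binary)
  truth <- data.frame(stratum = stratum, true_tau = true_tau, true_m = m_x,
                      y0 = y0, y1 = y1, stringsAsFactors = FALSE)
  structure(list(data = data, truth = truth, config = config),
            class = "synth_dataset")
}

#' Ground-truth complier-average effect of a synthetic trial
#'
#' The mean of the per-unit true success-probability difference over units
#' whose stratum is "complier" — the estimand every downstream LATE
#' estimator targets.
#'
#' @param ds A `synth_dataset` from [synth_generate()].
#' @return Scalar effect value.
#' @export
true_late <- function(ds) {
  stopifnot(inherits(ds, "synth_dataset"))
  sel <- ds$truth$stratum == "complier"
  if (!any(sel)) stopf("true_late: no compliers in the sample")
  mean(ds$truth$true_tau[sel])
}

#' Write a trial dataset (and ground truth) as delimited text
#'
#' Columns: `y`, `d`, `z`, optional `cluster`, then covariates, tab
#' separated with a header. For a `synth_dataset`, the per-unit ground
#' truth is written alongside with suffix `.truth`.
#'
#' @param ds A [trial_dataset()] or `synth_dataset`.
#' @param path Output file path.
#' @export
write_trial <- function(ds, path) {
  truth <- NULL
  if (inherits(ds, "synth_dataset")) {
    truth <- ds$truth
    ds <- ds$data
  }
  stopifnot(inherits(ds, "trial_dataset"))
  df <- data.frame(y = ds$y, d = ds$d, z = ds$z)
  if (!is.null(ds$cluster)) df$cluster <- ds$cluster
  df <- cbind(df, as.data.frame(ds$X))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth))
    write.table(truth, paste0(path, ".truth"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}
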