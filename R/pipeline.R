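#' Read a trial dataset from delimited text
#'
#' Expects tab-delimited text with a header, as written by
#' [write_trial()]. Rows with any missing value are dropped
#' (complete-case analysis) and the number of dropped rows is reported and
#' attached as an attribute.
#'
#' @param path Input file.
#' @param y,d,z Column names for outcome, treatment received and
#'   assignment.
#' @param cluster Optional cluster column name.
#' @param supply_tags Character vector of supply-side covariate columns.
#' @param allow_nonbinary_y Permit a non-binary outcome column.
#' @return A [trial_dataset()] with attribute `dropped_rows`.
#' @export
read_trial <- function(path, y = "y", d = "d", z = "z", cluster = NULL,
                       supply_tags = character(),
                       allow_nonbinary_y = FALSE) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  for (cn in c(y, d, z, cluster, supply_tags))
    if (!cn %in% names(df))
      stopf("read_trial: column '%s' not found in %s", cn, path)
  cc <- complete.cases(df)
  dropped <- sum(!cc)
  if (dropped > 0) {
    message(sprintf("read_trial: dropped %d incomplete row(s)", dropped))
    df <- df[cc, , drop = FALSE]
  }
  for (cn in c(d, z)) {
    bad <- which(!df[[cn]] %in% c(0, 1))
    if (length(bad))
      stopf("read_trial: column '%s' is not binary in row(s) %s", cn,
            paste(head(bad, 5), collapse = ", "))
  }
  if (!allow_nonbinary_y) {
    bad <- which(!df[[y]] %in% c(0, 1))
    if (length(bad))
      stopf("read_trial: column '%s' is not binary in row(s) %s", y,
            paste(head(bad, 5), collapse = ", "))
  }
  xcols <- setdiff(names(df), c(y, d, z, cluster))
  ds <- trial_dataset(df[[y]], df[[d]], df[[z]],
                      df[, xcols, drop = FALSE],
                      cluster = if (is.null(cluster)) NULL else df[[cluster]],
                      supply_tags = supply_tags,
                      allow_nonbinary_y = allow_nonbinary_y)
  attr(ds, "dropped_rows") <- dropped
  ds
}

#' Configure a full pipeline run
#'
#' Exactly one of `preset` (a [synth_preset()] name) or `input` (a file
#' readable by [read_trial()]) must be given.
#'
#' @param preset Synthetic preset name, or `NULL`.
#' @param n Units to generate when using a preset.
#' @param input Path to a delimited trial dataset, or `NULL`.
#' @param schema Named list passed to [read_trial()]
#'   (`y`, `d`, `z`, `cluster`, `supply_tags`).
#' @param params Base [forest_params()].
#' @param tuning_grid Optional hyperparameter grid for [tune_iv_forest()].
#' @param exclude_supply_from_e Drop supply-tagged columns from the
#'   treatment-propensity forest (automatically disabled, and logged, for
#'   untagged datasets).
#' @param blp_robust_se,clan_rank_by,vi_mode Heterogeneity-stage flags.
#' @param blp_reference Reference columns dropped in the BLP design.
#' @param policy_depths Policy-tree depths to learn.
#' @param seed Master seed for the run.
#' @return A `run_config`.
#' @export
run_config <- function(preset = NULL, n = 2000, input = NULL,
                       schema = list(), params = forest_params(),
                       tuning_grid = NULL, exclude_supply_from_e = TRUE,
                       blp_robust_se = TRUE,
                       clan_rank_by = c("gamma", "tau"),
                       vi_mode = c("frequency", "variance"),
                       blp_reference = NULL,
                       policy_depths = c(2, 3), seed = 1) {
  if (is.null(preset) == is.null(input))
    stopf("run_config: exactly one of 'preset' or 'input' must be set")
  structure(list(preset = preset, n = n, input = input, schema = schema,
                 params = params, tuning_grid = tuning_grid,
                 exclude_supply_from_e = exclude_supply_from_e,
                 blp_robust_se = blp_robust_se,
                 clan_rank_by = match.arg(clan_rank_by),
                 vi_mode = match.arg(vi_mode),
                 blp_reference = blp_reference,
                 policy_depths = policy_depths, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full instrumental-forest analysis pipeline
#'
#' Executes, in order: strata accounting and balance diagnostics, nuisance
#' estimation, (optional) hyperparameter tuning, the instrumental forest
#' with out-of-bag CLATEs, compliance scores, doubly robust scores, the
#' AIPW LATE and the 2SLS baseline, BLP, CLAN, variable importance, and
#' policy trees at the requested depths. Identical config and seed yield
#' an identical bundle.
#'
#' @param cfg A [run_config()].
#' @return A `report_bundle` list of every stage's output plus a manifest
#'   stub (config, seed, timings).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  stage <- "input"
  notes <- character()
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  synth <- NULL
  ds <- run_stage("input", {
    if (!is.null(cfg$preset)) {
      synth <- synth_generate(synth_preset(cfg$preset, n = cfg$n,
                                           seed = cfg$seed))
      synth$data
    } else {
      do.call(read_trial, c(list(path = cfg$input), cfg$schema))
    }
  })
  tick("input")

  exclude_e <- cfg$exclude_supply_from_e
  if (exclude_e && length(ds$supply_tags) == 0) {
    exclude_e <- FALSE
    notes <- c(notes, "no supply-tagged columns; exclude_supply_from_e disabled")
  }

  tab <- run_stage("strata", contingency(ds))
  shares <- strata_shares(tab)
  balance <- smd(ds, "z")
  tick("strata")

  params <- cfg$params
  params$seed <- as.integer(sub_seed(cfg$seed, 100))
  nu <- run_stage("nuisances",
                  estimate_nuisances(ds, params, exclude_supply_from_e = exclude_e))
  tick("nuisances")

  if (!is.null(cfg$tuning_grid)) {
    tuned <- run_stage("tune", tune_iv_forest(ds, nu, cfg$tuning_grid, params))
    params <- tuned$best
    tune_log <- tuned$log
  } else tune_log <- NULL
  tick("tune")

  model <- run_stage("iv_forest", iv_forest(ds, nu, params))
  clates <- predict_clate(model)
  tick("iv_forest")

  cs <- run_stage("compliance", compliance_score(ds, params))
  dr <- run_stage("dr_scores", dr_score(ds, clates, nu, cs))
  late_est <- late(dr)
  tsls <- run_stage("tsls", baseline_2sls(ds))
  tick("scores")

  blp_ref <- if (is.null(cfg$blp_reference)) default_reference(colnames(ds$X))
             else cfg$blp_reference
  blp_res <- run_stage("blp", blp(dr, ds$X, reference = blp_ref,
                                  robust = cfg$blp_robust_se))
  clan_res <- run_stage("clan", clan(dr, ds$X,
                                     rank_scores = if (cfg$clan_rank_by == "tau")
                                       clates$tau_hat else NULL))
  vi <- run_stage("vi", variable_importance(model, mode = cfg$vi_mode))
  tick("heterogeneity")

  policy <- run_stage("policy", lapply(cfg$policy_depths, function(d) {
    tr <- learn_policy_tree(ds$X, dr, depth = d)
    list(depth = d, tree = tr, value = policy_value(tr, ds$X, dr))
  }))
  names(policy) <- paste0("depth", cfg$policy_depths)
  tick("policy")

  structure(
    list(dataset = ds, synth = synth, contingency = tab, shares = shares,
         smd = balance, nuisances = nu, tune_log = tune_log, params = params,
         model = model, clates = clates, compliance = cs, dr = dr,
         late = late_est, tsls = tsls, blp = blp_res, clan = clan_res,
         vi = vi, policy = policy,
         manifest = list(config = cfg, seed = cfg$seed, notes = notes,
                         timings = timings,
                         package_version = as.character(utils::packageVersion("cctforest")))),
    class = "report_bundle")
}

#' Write a report bundle to a directory
#'
#' Emits every table as tab-delimited text, trees and the manifest as
#' JSON; the manifest (with an md5 hash of every emitted file) is written
#' last as the completion marker. Refuses to overwrite an existing report
#' unless `overwrite = TRUE`.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param path Output directory.
#' @param overwrite Replace an existing report.
#' @param plots Also attempt a CLATE histogram PNG (skipped silently when
#'   no graphics device is available).
#' @return The manifest path, invisibly.
#' @export
write_report <- function(bundle, path, overwrite = FALSE, plots = FALSE) {
  stopifnot(inherits(bundle, "report_bundle"))
  manifest_path <- file.path(path, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stopf("write_report: report already exists at %s (use overwrite = TRUE)", path)
  needed <- c("shares", "smd", "clates", "dr", "late", "tsls", "blp",
              "clan", "vi", "policy")
  miss <- needed[vapply(needed, function(f) is.null(bundle[[f]]), logical(1))]
  if (length(miss))
    stopf("write_report: bundle is missing component(s): %s",
          paste(miss, collapse = ", "))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, file) {
    write.table(df, file.path(path, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
    file
  }
  files <- character()
  cnt <- unclass(bundle$contingency); attr(cnt, "percent") <- NULL
  files <- c(files, tsv(as.data.frame(cnt), "contingency.tsv"))
  files <- c(files, tsv(data.frame(
    stratum = c("complier", "always", "never"),
    share = c(bundle$shares$p_complier, bundle$shares$p_always,
              bundle$shares$p_never),
    rounding = bundle$shares$rounding), "strata.tsv"))
  files <- c(files, tsv(bundle$smd, "smd.tsv"))
  files <- c(files, tsv(as.data.frame(bundle$clates), "clates.tsv"))
  files <- c(files, tsv(as.data.frame(bundle$dr), "gamma.tsv"))
  lf <- function(l) data.frame(method = l$method, estimate = l$tau_hat,
                               se = l$se, ci_lo = l$ci95[1],
                               ci_hi = l$ci95[2], n = l$n)
  files <- c(files, tsv(rbind(lf(bundle$late), lf(bundle$tsls)), "late.tsv"))
  files <- c(files, tsv(as.data.frame(bundle$blp), "blp.tsv"))
  files <- c(files, tsv(as.data.frame(bundle$clan), "clan.tsv"))
  files <- c(files, tsv(as.data.frame(bundle$vi), "vi.tsv"))
  if (!is.null(bundle$tune_log))
    files <- c(files, tsv(bundle$tune_log, "tuning.tsv"))
  for (nm in names(bundle$policy)) {
    pj <- paste0("policy_", nm, ".json")
    policy_to_json(bundle$policy[[nm]]$tree, file.path(path, pj))
    files <- c(files, pj)
  }
  ef <- file.path(path, "e_forest.json")
  forest_to_json(bundle$nuisances$e_forest, ef)
  files <- c(files, "e_forest.json")
  if (plots) {
    draw <- function(file, expr) {
      ok <- try({
        grDevices::png(file.path(path, file), width = 700, height = 500)
        on.exit(grDevices::dev.off(), add = TRUE)
        expr
      }, silent = TRUE)
      if (!inherits(ok, "try-error")) files <<- c(files, file)
    }
    draw("clate_histogram.png", {
      graphics::hist(bundle$clates$tau_hat, breaks = 30,
                     main = "Estimated conditional LATEs",
                     xlab = "tau_hat(x)")
      graphics::abline(v = bundle$late$tau_hat, lty = 2)
    })
    whisker <- function(est, lo, hi, labels, main) {
      k <- length(est)
      graphics::plot(est, seq_len(k), xlim = range(c(lo, hi)),
                     yaxt = "n", ylab = "", xlab = "estimate (95% CI)",
                     pch = 19, main = main)
      graphics::segments(lo, seq_len(k), hi, seq_len(k))
      graphics::abline(v = 0, lty = 3)
      graphics::axis(2, at = seq_len(k), labels = labels, las = 2,
                     cex.axis = 0.6)
    }
    draw("blp.png", whisker(bundle$blp$estimate, bundle$blp$ci_lo,
                            bundle$blp$ci_hi, bundle$blp$term,
                            "Best linear predictors of Gamma"))
    draw("clan.png", whisker(bundle$clan$difference, bundle$clan$ci_lo,
                             bundle$clan$ci_hi, bundle$clan$variable,
                             "CLAN most vs least affected"))
  }
  hashes <- as.list(tools::md5sum(file.path(path, files)))
  names(hashes) <- files
  manifest <- list(files = hashes,
                   seed = bundle$manifest$seed,
                   notes = bundle$manifest$notes,
                   timings = as.list(bundle$manifest$timings),
                   package_version = bundle$manifest$package_version,
                   late = bundle$late$tau_hat,
                   mean_gamma = mean(bundle$dr$gamma))
  writeLines(jsonlite::toJSON(manifest, digits = NA, auto_unbox = TRUE),
             manifest_path)
  invisible(manifest_path)
}
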