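#' Honest forest hyperparameters
#'
#' Parameters shared by the nuisance regression forests and the
#' instrumental forest. Defaults follow community practice for honest,
#' subsampled ensembles: 2000 trees, `mtry = min(p, ceiling(sqrt(p)) + 20)`
#' (resolved at fit time when `NULL`), half the data subsampled per tree
#' without replacement, half of each subsample used to place splits
#' (honesty), a minimum child share `alpha = 0.05` of the parent, and a
#' minimum node size of 5 structure units.
#'
#' @param num_trees Number of trees in the ensemble.
#' @param mtry Covariates tried per split; `NULL` resolves the default.
#' @param sample_fraction Subsample share per tree, in (0, 1]. Out-of-bag
#'   prediction requires a value strictly below 1.
#' @param honesty_fraction Share of each subsample used to place splits,
#'   in (0, 1); the remainder estimates leaf quantities.
#' @param alpha Minimum child share of the parent node, in (0, 0.25].
#' @param min_node_size Minimum structure-half units per child. `NULL`
#'   resolves at fit time: 5 for regression forests; `max(5, ceiling(n /
#'   100))` for instrumental forests, so that local 2SLS leaves grow with
#'   the sample and per-leaf moment noise contracts.
#' @param seed Integer seed; fully determines the ensemble.
#' @return A `forest_params` list.
#' @export
forest_params <- function(num_trees = 2000, mtry = NULL,
                          sample_fraction = 0.5, honesty_fraction = 0.5,
                          alpha = 0.05, min_node_size = NULL, seed = 1) {
  if (num_trees < 1) stopf("forest_params: num_trees must be >= 1")
  if (sample_fraction <= 0 || sample_fraction > 1)
    stopf("forest_params: sample_fraction must be in (0, 1]")
  if (honesty_fraction <= 0 || honesty_fraction >= 1)
    stopf("forest_params: honesty_fraction must be in (0, 1)")
  if (alpha <= 0 || alpha > 0.25)
    stopf("forest_params: alpha must be in (0, 0.25]")
  if (!is.null(min_node_size) && min_node_size < 1)
    stopf("forest_params: min_node_size must be >= 1")
  if (!is.null(mtry) && mtry < 1) stopf("forest_params: mtry must be >= 1")
  structure(list(num_trees = as.integer(num_trees), mtry = mtry,
                 sample_fraction = sample_fraction,
                 honesty_fraction = honesty_fraction, alpha = alpha,
                 min_node_size = if (is.null(min_node_size)) NULL
                                 else as.integer(min_node_size),
                 seed = as.integer(seed)),
            class = "forest_params")
}

resolve_params <- function(params, p, n = NULL, type = "regression") {
  if (is.null(params$mtry)) params$mtry <- min(p, ceiling(sqrt(p)) + 20L)
  params$mtry <- as.integer(min(params$mtry, p))
  if (is.null(params$min_node_size)) {
    params$min_node_size <-
      if (type == "instrumental") max(5L, as.integer(ceiling(n / 100)))
      else 5L
  }
  params
}

new_forest <- function(trees, params, type, X, R) {
  structure(list(trees = trees, params = params, type = type,
                 feature_names = colnames(X), n_train = nrow(X),
                 X = X, R = R),
            class = "honest_forest")
}

#' Fit an honest regression forest
#'
#' CART-style splits minimising within-child variance of the target,
#' placed on the structure half of each subsample; leaf values are
#' estimation-half means (honesty). Deterministic given the seed.
#'
#' @param X Covariate matrix or data frame (no missing values).
#' @param y Numeric target.
#' @param params A [forest_params()].
#' @return An object of class `honest_forest`.
#' @export
regression_forest <- function(X, y, params = forest_params()) {
  X <- as_feature_matrix(X)
  if (anyNA(X) || anyNA(y)) stopf("regression_forest: missing values not allowed")
  if (length(y) != nrow(X)) stopf("regression_forest: length(y) != nrow(X)")
  if (nrow(X) < 4) stopf("regression_forest: too few units")
  params <- resolve_params(params, ncol(X), nrow(X), "regression")
  if (var(y) == 0)
    warning("constant target: every tree is a single leaf", call. = FALSE)
  trees <- cpp_grow_forest(X, cbind(y), 0L, unclass(params))
  new_forest(trees, params, "regression", X, cbind(ytarget = y))
}

#' Predictions from an honest forest
#'
#' For a regression forest, the average of leaf (estimation-half) means over
#' all trees. For new profiles every tree contributes; use [predict_oob()]
#' for training units.
#'
#' @param object An `honest_forest`.
#' @param newdata Covariate matrix with the training schema.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.honest_forest <- function(object, newdata, ...) {
  newdata <- check_schema(object$feature_names, newdata)
  acc <- cpp_accumulate(object$trees, newdata,
                        rep(0L, nrow(newdata)), FALSE, object$n_train)
  if (object$type != "regression")
    stopf("predict: use predict_clate() for instrumental forests")
  out <- acc$stats[, 1]
  out[acc$count == 0] <- NA_real_
  out
}

check_schema <- function(feature_names, newdata) {
  newdata <- as_feature_matrix(newdata)
  if (!all(feature_names %in% colnames(newdata)))
    stopf("covariate schema mismatch; missing: %s",
          paste(setdiff(feature_names, colnames(newdata)), collapse = ", "))
  newdata[, feature_names, drop = FALSE]
}

#' Out-of-bag predictions for training units
#'
#' Averages leaf values over the trees whose subsample excludes each unit.
#' Units that appear in every subsample (possible only with very few trees)
#' get `NA` and are flagged via the `"missing_oob"` attribute.
#'
#' @param forest An `honest_forest` (regression type).
#' @return Numeric vector of OOB predictions, one per training unit.
#' @export
predict_oob <- function(forest) {
  stopifnot(inherits(forest, "honest_forest"))
  if (forest$params$sample_fraction >= 1)
    stopf("predict_oob: sample_fraction = 1 leaves no out-of-bag trees")
  acc <- cpp_accumulate(forest$trees, forest$X,
                        seq_len(forest$n_train), TRUE, forest$n_train)
  out <- acc$stats[, 1]
  miss <- acc$count == 0
  out[miss] <- NA_real_
  attr(out, "missing_oob") <- which(miss)
  out
}

oob_moments <- function(forest, Xtarget = NULL, target_ids = NULL) {
  if (is.null(Xtarget)) {
    Xtarget <- forest$X
    target_ids <- seq_len(forest$n_train)
    oob <- TRUE
  } else {
    target_ids <- rep(0L, nrow(Xtarget))
    oob <- FALSE
  }
  cpp_accumulate(forest$trees, Xtarget, as.integer(target_ids), oob,
                 forest$n_train)
}

#' Similarity weights of an honest forest
#'
#' The weight of training unit i at profile x is the average over trees of
#' `1 / leaf size` if i sits in the same leaf as x within the tree's
#' estimation half, else 0. Weights are non-negative and sum to 1 (within
#' 1e-10) whenever at least one tree contributes.
#'
#' @param forest An `honest_forest`.
#' @param x A single profile (vector) or matrix of profiles.
#' @param oob For training units (rows of the training matrix passed with
#'   `target_ids`), restrict to out-of-bag trees.
#' @param target_ids Optional 1-based training ids matching rows of `x`.
#' @return Matrix of weights, one row per profile, one column per training
#'   unit.
#' @export
forest_weights <- function(forest, x, oob = FALSE, target_ids = NULL) {
  stopifnot(inherits(forest, "honest_forest"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, forest$feature_names))
  x <- check_schema(forest$feature_names, x)
  if (is.null(target_ids)) target_ids <- rep(0L, nrow(x))
  cpp_forest_weights(forest$trees, forest$X, x, as.integer(target_ids), oob)
}

all_single_leaf <- function(trees) {
  all(vapply(trees, function(tr) is.na(tr$var[1]), logical(1)))
}

# ---- serialisation -------------------------------------------------------

#' Serialise a forest to a JSON text file
#'
#' Stores trees (splits, leaf statistics, subsample and estimation-half
#' indices), parameters, type and the training schema at full numeric
#' precision, so reloaded forests predict bit-identically on new profiles.
#' The training data itself is not serialised.
#'
#' @param forest An `honest_forest`.
#' @param path Output path; when `NULL`, the JSON string is returned.
#' @return The path (invisibly) or the JSON string.
#' @export
forest_to_json <- function(forest, path = NULL) {
  stopifnot(inherits(forest, "honest_forest"))
  enc_tree <- function(tr) {
    tr$stats <- as.vector(tr$stats) # column-major flat; nrow = length(var)
    tr
  }
  obj <- list(type = forest$type,
              params = unclass(forest$params),
              feature_names = forest$feature_names,
              n_train = forest$n_train,
              trees = lapply(forest$trees, enc_tree))
  js <- jsonlite::toJSON(obj, digits = I(17), na = "null", auto_unbox = FALSE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Reload a forest serialised with [forest_to_json()]
#'
#' @param path Path to the JSON file (or a JSON string).
#' @return An `honest_forest` without training data attached; prediction on
#'   new profiles is bit-identical to the original forest.
#' @export
forest_from_json <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path), collapse = "") else path
  obj <- jsonlite::fromJSON(txt, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  dec_tree <- function(tr) {
    var <- as.integer(tr$var)
    list(var = var, threshold = as.numeric(tr$threshold),
         left = as.integer(tr$left), right = as.integer(tr$right),
         depth = as.integer(tr$depth), gain = as.numeric(tr$gain),
         tau = as.numeric(tr$tau),
         n_struct = as.integer(tr$n_struct), n_est = as.integer(tr$n_est),
         stats = matrix(as.numeric(tr$stats), nrow = length(var)),
         subsample = as.integer(tr$subsample),
         est_units = as.integer(tr$est_units))
  }
  trees <- lapply(obj$trees, dec_tree)
  pp <- lapply(obj$params[c("num_trees", "mtry", "sample_fraction",
                            "honesty_fraction", "alpha", "min_node_size",
                            "seed")], function(v) if (length(v)) v[[1]] else NULL)
  params <- do.call(forest_params, pp)
  structure(list(trees = trees, params = params, type = obj$type[[1]],
                 feature_names = as.character(obj$feature_names),
                 n_train = as.integer(obj$n_train)[[1]],
                 X = NULL, R = NULL),
            class = "honest_forest")
}

#' Leaf membership of profiles in every tree
#'
#' Mainly a testing/inspection aid: the 1-based node id each profile
#' reaches in each tree.
#'
#' @param forest An `honest_forest`.
#' @param x Profile matrix.
#' @return Integer matrix, profiles by trees.
#' @export
leaf_ids <- function(forest, x) {
  x <- check_schema(forest$feature_names, x)
  cpp_leaf_ids(forest$trees, x)
}
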