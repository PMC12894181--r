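make_xy <- function(n, seed = 1) {
  set.seed(seed)
  X <- cbind(x1 = rbinom(n, 1, 0.5), x2 = rbinom(n, 1, 0.5),
             x3 = runif(n))
  list(X = X, y = X[, "x1"] + 0.2 * X[, "x2"] + rnorm(n, 0, 0.3))
}

test_that("parameter bounds are enforced at construction", {
  expect_error(forest_params(alpha = 0.3), "alpha")
  expect_error(forest_params(honesty_fraction = 1), "honesty_fraction")
  expect_error(forest_params(sample_fraction = 0), "sample_fraction")
  expect_error(forest_params(num_trees = 0), "num_trees")
})

test_that("a constant target warns and predicts the constant everywhere", {
  X <- matrix(rbinom(200, 1, 0.5), 100, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(f <- regression_forest(X, rep(3, 100), quick_params(20)),
                 "constant")
  expect_true(all(predict(f, X) == 3))
  expect_true(all(predict_oob(f) == 3, na.rm = TRUE))
})

test_that("OOB predictions recover group means of a binary signal", {
  dd <- make_xy(2000)
  y <- dd$X[, "x1"] # target IS the binary covariate
  f <- regression_forest(dd$X, y, quick_params(100))
  p <- predict_oob(f)
  expect_lt(max(abs(p[y == 1] - 1)), 0.05)
  expect_lt(max(abs(p[y == 0] - 0)), 0.05)
})

test_that("min_node_size = n degenerates to subsample means", {
  dd <- make_xy(300)
  f <- regression_forest(dd$X, dd$y, quick_params(30, min_node_size = 300))
  # single-leaf trees: identical prediction at any profile
  p <- predict(f, dd$X[1:5, ])
  expect_true(all(abs(p - p[1]) < 1e-12))
  # the single tree's value is its estimation-half mean
  tr <- f$trees[[1]]
  expect_true(is.na(tr$var[1]))
  expect_equal(tr$stats[1, 1], mean(dd$y[tr$est_units]))
})

test_that("forests are deterministic in the seed and vary across seeds", {
  dd <- make_xy(400)
  f1 <- regression_forest(dd$X, dd$y, quick_params(10, seed = 7))
  f2 <- regression_forest(dd$X, dd$y, quick_params(10, seed = 7))
  f3 <- regression_forest(dd$X, dd$y, quick_params(10, seed = 8))
  expect_identical(f1$trees, f2$trees)
  expect_false(identical(f1$trees[[1]]$subsample, f3$trees[[1]]$subsample))
})

test_that("honesty: leaf values are estimation-half means only", {
  dd <- make_xy(500, seed = 3)
  f <- regression_forest(dd$X, dd$y, quick_params(10, seed = 2))
  ids <- leaf_ids(f, dd$X)
  for (t in 1:5) {
    tr <- f$trees[[t]]
    leaves <- which(is.na(tr$var))
    for (lf in leaves) {
      est_here <- tr$est_units[ids[tr$est_units, t] == lf]
      if (length(est_here) > 0)
        expect_equal(tr$stats[lf, 1], mean(dd$y[est_here]))
    }
    # structure and estimation halves are disjoint
    su <- setdiff(tr$subsample, tr$est_units)
    expect_length(intersect(su, tr$est_units), 0)
  }
})

test_that("out-of-bag bookkeeping flags unavailable units and full subsamples", {
  dd <- make_xy(200)
  f_full <- regression_forest(dd$X, dd$y, quick_params(5, sample_fraction = 1))
  expect_error(predict_oob(f_full), "out-of-bag")
  f1 <- regression_forest(dd$X, dd$y, quick_params(1, seed = 4))
  p <- predict_oob(f1)
  inbag <- f1$trees[[1]]$subsample
  expect_true(all(is.na(p[inbag])))
  expect_setequal(attr(p, "missing_oob"), inbag)
  # with many trees every unit has at least one OOB tree
  f <- regression_forest(dd$X, dd$y, quick_params(100))
  expect_length(attr(predict_oob(f), "missing_oob"), 0)
})

test_that("similarity weights are a proper distribution concentrated in-leaf", {
  dd <- make_xy(400, seed = 5)
  f <- regression_forest(dd$X, dd$y, quick_params(30, seed = 5))
  W <- forest_weights(f, dd$X[1:10, ])
  expect_true(all(W >= 0))
  expect_true(all(abs(rowSums(W) - 1) < 1e-10))

  # single-leaf single-tree forest: uniform over the estimation half
  fs <- regression_forest(dd$X, dd$y, quick_params(1, min_node_size = 400))
  w <- forest_weights(fs, dd$X[1, , drop = FALSE])[1, ]
  est <- fs$trees[[1]]$est_units
  expect_equal(unname(w[est]), rep(1 / length(est), length(est)))
  expect_true(all(w[-est] == 0))
})

test_that("weights concentrate on the target's cluster", {
  set.seed(6)
  n <- 400
  X <- cbind(g = rep(c(0, 1), each = n / 2), noise = rbinom(n, 1, 0.5))
  y <- 3 * X[, "g"] + rnorm(n, 0, 0.1)
  f <- regression_forest(X, y, quick_params(50, seed = 6))
  w <- forest_weights(f, c(g = 0, noise = 1))[1, ]
  expect_gte(sum(w[X[, "g"] == 0]), 0.9)
})

test_that("serialised forests reload and predict bit-identically", {
  dd <- make_xy(300, seed = 9)
  f <- regression_forest(dd$X, dd$y, quick_params(15, seed = 9))
  path <- tempfile(fileext = ".json")
  forest_to_json(f, path)
  f2 <- forest_from_json(path)
  Xnew <- make_xy(50, seed = 10)$X
  expect_identical(predict(f, Xnew), predict(f2, Xnew))
  expect_identical(f$trees, f2$trees)
})

test_that("prediction demands the training schema", {
  dd <- make_xy(100)
  f <- regression_forest(dd$X, dd$y, quick_params(5))
  bad <- dd$X[, 1:2]
  expect_error(predict(f, bad), "schema")
})
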