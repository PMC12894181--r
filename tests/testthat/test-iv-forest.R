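test_that("instrument propensity estimates centre on the assignment rate", {
  ds <- synth_generate(synth_preset("pkh2009", n = 4000, seed = 1))$data
  nu <- estimate_nuisances(ds, quick_params(60))
  expect_gt(mean(nu$g_hat), 0.45)
  expect_lt(mean(nu$g_hat), 0.55)
  expect_true(all(nu$e_hat >= 0.01 & nu$e_hat <= 0.99))
  expect_true(all(nu$g_hat >= 0.01 & nu$g_hat <= 0.99))
})

test_that("the treatment-propensity forest never sees supply-tagged columns", {
  ds <- synth_generate(synth_preset("pkh2009", n = 1500, seed = 2))$data
  nu <- estimate_nuisances(ds, quick_params(30))
  used <- nu$e_forest$feature_names
  expect_length(intersect(used, ds$supply_tags), 0)
  # structural check on the stored trees: every split var is untagged
  for (tr in nu$e_forest$trees[1:10]) {
    vars <- used[tr$var[!is.na(tr$var)]]
    expect_length(intersect(vars, ds$supply_tags), 0)
  }
  # an untagged dataset with the flag set must demand tags
  ds2 <- synth_generate(synth_preset("planted_binary", n = 200, seed = 2))$data
  expect_error(estimate_nuisances(ds2, quick_params(5)), "supply")
  expect_s3_class(estimate_nuisances(ds2, quick_params(5),
                                     exclude_supply_from_e = FALSE),
                  "nuisances")
})

test_that("a constant outcome gives a constant conditional mean", {
  ds <- synth_generate(synth_preset("planted_binary", n = 300, seed = 3))$data
  ds$y <- rep(1, ds$n)
  nu <- suppressWarnings(estimate_nuisances(ds, quick_params(10),
                                            exclude_supply_from_e = FALSE))
  expect_true(all(nu$m_hat == 1))
})

test_that("residualisation is elementwise subtraction", {
  y <- c(1, 0, 1, 0); d <- c(1, 1, 0, 0); z <- c(1, 0, 1, 0)
  ds <- trial_dataset(y, d, z, cbind(x = c(0, 1, 0, 1)))
  nu <- fake_nuisances(m_hat = c(0.5, 0.25, 0.75, 0.5),
                       e_hat = c(0.4, 0.6, 0.4, 0.6),
                       g_hat = rep(0.5, 4))
  r <- residualise(ds, nu)
  expect_equal(r$ytil, c(0.5, -0.25, 0.25, -0.5))
  expect_equal(r$dtil, c(0.6, 0.4, -0.4, -0.6))
  expect_equal(r$ztil, c(0.5, -0.5, 0.5, -0.5))
  nu$m_hat <- ds$y
  expect_true(all(residualise(ds, nu)$ytil == 0))
  nu$m_hat <- c(0.1, 0.2)
  expect_error(residualise(ds, nu), "match")
})

test_that("leaf_wald is the covariance-ratio estimate with degenerate marker", {
  # identity effect: ytil == dtil
  dt <- c(1, 0, 1, 1, 0); zt <- c(1, 0, 0, 1, 1)
  expect_equal(leaf_wald(dt, dt, zt), 1)
  # hand Wald from printed two-arm marginals: ITT / first stage
  ds <- grouped_trial(1028, 99, 0.644, 1037, 512, 0.700)
  itt <- 0.700 - 0.644
  fs <- 512 / 1037 - 99 / 1028
  expect_equal(leaf_wald(ds$y, ds$d, ds$z), itt / fs, tolerance = 1e-12)
  expect_equal(round(itt / fs, 3), 0.141)
  # orthogonal instrument: zero denominator
  out <- leaf_wald(c(1, 2, 3, 4), c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_true(is.na(out))
  expect_true(attr(out, "degenerate"))
  expect_error(leaf_wald(1, 1, 1), "length")
})

test_that("single-leaf instrumental forests reproduce the global Wald estimate", {
  ds <- synth_generate(synth_preset("pkh2009", n = 500, seed = 4))$data
  nu <- estimate_nuisances(ds, quick_params(40, seed = 4))
  m <- iv_forest(ds, nu, quick_params(40, min_node_size = 500, seed = 4))
  cl <- predict_clate(m)
  expect_lt(max(abs(cl$tau_hat - m$global_tau)), 1e-8)
  # same for new profiles
  cl2 <- predict_clate(m, ds$X[1:20, ])
  expect_lt(max(abs(cl2$tau_hat - m$global_tau)), 1e-8)
})

test_that("weighted-moment predictions agree with explicit similarity weights", {
  ds <- synth_generate(synth_preset("planted_binary", n = 600, seed = 5))$data
  nu <- estimate_nuisances(ds, quick_params(30, seed = 5),
                           exclude_supply_from_e = FALSE)
  m <- iv_forest(ds, nu, quick_params(30, seed = 5))
  targets <- ds$X[1:5, , drop = FALSE]
  cl <- predict_clate(m, targets)
  W <- forest_weights(m$forest, targets)
  r <- m$residuals
  for (j in 1:5) {
    tau_w <- weighted_wald(r$ytil, r$dtil, r$ztil, W[j, ])
    expect_equal(cl$tau_hat[j], as.numeric(tau_w), tolerance = 1e-10)
  }
  # uniform weights collapse to the full-sample leaf_wald
  expect_equal(as.numeric(weighted_wald(r$ytil, r$dtil, r$ztil,
                                        rep(1, ds$n))),
               as.numeric(leaf_wald(r$ytil, r$dtil, r$ztil)))
})

test_that("homogeneous effects yield tight CLATEs that tighten with n", {
  sds <- vapply(c(1000, 2000, 4000), function(n) {
    ds <- synth_generate(synth_preset("homogeneous", n = n, seed = 6))$data
    nu <- estimate_nuisances(ds, quick_params(300, seed = 6))
    m <- iv_forest(ds, nu, quick_params(300, seed = 6))
    sd(predict_clate(m)$tau_hat)
  }, 0)
  expect_lt(sds[3], 0.1)
  expect_true(all(diff(sds) < 0))
})

test_that("a planted binary modifier is recovered in the CLATE contrast", {
  ds <- synth_generate(synth_preset("planted_binary", n = 4000, seed = 7))$data
  nu <- estimate_nuisances(ds, quick_params(100, seed = 7),
                           exclude_supply_from_e = FALSE)
  m <- iv_forest(ds, nu, quick_params(100, seed = 7))
  tau <- predict_clate(m)$tau_hat
  x1 <- ds$X[, "x1"]
  expect_gte(mean(tau[x1 == 1]) - mean(tau[x1 == 0]), 0.2)
})

test_that("a weak instrument aborts forest growth", {
  set.seed(8)
  n <- 300
  # no one takes treatment: Dtil is constant, the root moment is exactly zero
  ds <- trial_dataset(rbinom(n, 1, 0.5), rep(0L, n),
                      rep(c(0L, 1L), length.out = n),
                      cbind(x = rbinom(n, 1, 0.5)))
  nu <- fake_nuisances(rep(mean(ds$y), n), rep(0.5, n), rep(0.5, n))
  expect_error(iv_forest(ds, nu, quick_params(5)), "weak instrument")
})

test_that("tuning selects by the out-of-bag moment loss with stable ties", {
  ds <- synth_generate(synth_preset("planted_binary", n = 2000, seed = 9))$data
  nu <- estimate_nuisances(ds, quick_params(40, seed = 9),
                           exclude_supply_from_e = FALSE)
  one <- tune_iv_forest(ds, nu, data.frame(mtry = 3), quick_params(30, seed = 9))
  expect_equal(one$best_index, 1L)
  expect_equal(one$best$mtry, 3L)
  # the selection is the score minimum of the logged grid
  two <- tune_iv_forest(ds, nu,
                        data.frame(min_node_size = c(20, 400)),
                        quick_params(30, seed = 9))
  expect_equal(two$best_index, which.min(two$log$score))
  # identical candidates: the first wins by tie-break order
  tie <- tune_iv_forest(ds, nu, data.frame(mtry = c(5, 5)),
                        quick_params(10, seed = 9))
  expect_equal(tie$best_index, 1L)
  expect_error(tune_iv_forest(ds, nu, data.frame()[0, ]), "empty")
})

test_that("the tuning objective prefers a model that can see the modifier", {
  ds <- synth_generate(synth_preset("planted_binary", n = 4000, seed = 9))$data
  p <- quick_params(60, seed = 9)
  nu <- estimate_nuisances(ds, p, exclude_supply_from_e = FALSE)
  res <- residualise(ds, nu)
  # oracle = direct evaluation of the squared empirical moment violation
  violation <- function(model) {
    tau <- predict_clate(model)$tau_hat
    mean(((res$ytil - tau * res$dtil) * res$ztil)^2)
  }
  full <- iv_forest(ds, nu, p)
  blind <- ds
  blind$X <- ds$X[, setdiff(colnames(ds$X), "x1")] # cannot see the modifier
  expect_lt(violation(full), violation(iv_forest(blind, nu, p)))
})

test_that("clate prediction is deterministic and summarised", {
  ds <- synth_generate(synth_preset("pkh2009", n = 800, seed = 10))$data
  nu <- estimate_nuisances(ds, quick_params(20, seed = 10))
  m <- iv_forest(ds, nu, quick_params(20, seed = 10))
  a <- predict_clate(m); b <- predict_clate(m)
  expect_identical(a$tau_hat, b$tau_hat)
  s <- attr(a, "summary")
  expect_equal(unname(s["mean"]), mean(a$tau_hat))
})
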