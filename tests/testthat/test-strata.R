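test_that("contingency counts equal a brute-force double loop", {
  set.seed(42)
  d <- rbinom(50, 1, 0.4); z <- rbinom(50, 1, 0.5); y <- rbinom(50, 1, 0.5)
  ds <- trial_dataset(y, d, z, matrix(0, 50, 1, dimnames = list(NULL, "x")))
  tab <- contingency(ds)
  for (dv in 0:1) for (zv in 0:1) {
    cnt <- 0L
    for (i in 1:50) if (d[i] == dv && z[i] == zv) cnt <- cnt + 1L
    expect_identical(unclass(tab)[dv + 1, zv + 1], cnt)
  }
  # invariant to row order
  o <- sample(50)
  ds2 <- trial_dataset(y[o], d[o], z[o], matrix(0, 50, 1,
                                                dimnames = list(NULL, "x")))
  expect_equal(unclass(contingency(ds2)), unclass(tab))
})

test_that("all-control enrolment yields an empty enrolled row", {
  ds <- trial_dataset(rbinom(20, 1, 0.5), rep(0, 20), rep(c(0, 1), 10),
                      matrix(0, 20, 1, dimnames = list(NULL, "x")))
  tab <- contingency(ds)
  expect_equal(unname(unclass(tab)["enrolled", ]), c(0L, 0L))
})

test_that("strata shares follow the one-decimal-percent reporting convention", {
  t09 <- crosstab(929, 99, 525, 512)
  s09 <- strata_shares(t09)
  expect_equal(s09$p_always, 9.6)
  expect_equal(s09$p_never, 50.6)
  expect_equal(s09$p_complier, 39.8)
  t13 <- crosstab(884, 140, 501, 464)
  s13 <- strata_shares(t13)
  expect_equal(s13$p_always, 13.7)
  expect_equal(s13$p_never, 51.9)
  expect_equal(s13$p_complier, 34.4)
})

test_that("raw complier share equals the first-stage difference exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- rbinom(200, 1, 0.5); z <- rbinom(200, 1, 0.5)
    ds <- trial_dataset(rbinom(200, 1, 0.5), d, z,
                        matrix(0, 200, 1, dimnames = list(NULL, "x")))
    s <- suppressWarnings(strata_shares(contingency(ds), "raw"))
    expect_equal(s$p_complier, mean(d[z == 1]) - mean(d[z == 0]))
    expect_equal(s$p_always + s$p_never +
                   (mean(d[z == 1]) - mean(d[z == 0])), 1,
                 tolerance = 1e-12)
  }
})

test_that("perfect compliance gives an all-complier decomposition", {
  z <- rep(c(0, 1), 50)
  ds <- trial_dataset(rbinom(100, 1, 0.5), z, z,
                      matrix(0, 100, 1, dimnames = list(NULL, "x")))
  s <- strata_shares(contingency(ds), "raw")
  expect_equal(c(s$p_always, s$p_never, s$p_complier), c(0, 0, 1))
})

test_that("monotonicity violations warn and are flagged", {
  # enrolment more common under control than treatment
  tab <- crosstab(50, 50, 90, 10)
  expect_warning(s <- strata_shares(tab, "raw"), "monotonicity")
  expect_true(s$monotonicity_violation)
  expect_lt(s$p_complier, 0)
  expect_error(strata_shares(crosstab(0, 0, 10, 10)), "empty")
})

test_that("smd matches hand arithmetic and flags degenerate columns", {
  z <- c(rep(0, 5), rep(1, 5))
  v <- c(0, 0, 0, 0, 1, 0, 0, 1, 1, 1) # means 0.2 vs 0.6
  ds <- trial_dataset(v, rbinom(10, 1, 0.5), z,
                      cbind(v = v, flat = rep(1, 10)))
  out <- smd(ds, "z")
  # pooled SD = sqrt((0.2 + 0.3)/2) = 0.5; (0.6 - 0.2)/0.5 = 0.8
  expect_equal(out$smd[out$variable == "v"], 0.8)
  expect_equal(out$smd[out$variable == "flat"], 0)
  expect_true(out$zero_variance[out$variable == "flat"])
})

test_that("identical groups have zero smd and single-group data errors", {
  # covariate and outcome have the same distribution in both arms
  z <- rep(c(0, 1), 20)
  a <- rep(c(0, 1, 1, 0), 10)
  ds <- trial_dataset(a, rep(c(0, 1), 20), z, cbind(a = a))
  out <- smd(ds, "z")
  expect_true(all(out$smd == 0))
  ds1 <- trial_dataset(rbinom(10, 1, 0.5), rbinom(10, 1, 0.5), rep(1, 10),
                       cbind(a = a[1:10]))
  expect_error(smd(ds1, "z"), "non-empty")
})

test_that("randomised assignment is balanced below the 0.1 SMD threshold", {
  worst <- vapply(1:20, function(seed) {
    ds <- synth_generate(synth_preset("pkh2009", n = 5000, seed = seed))$data
    max(abs(smd(ds, "z")$smd[-1])) # covariates only; y responds to D
  }, 0)
  expect_true(mean(worst < 0.1) >= 0.9)
})

test_that("tercile encoding partitions with ties to the lower tercile", {
  t1 <- tercile_encode(1:9, "v")
  expect_equal(unname(colSums(t1)), c(3, 3, 3))
  expect_equal(which(t1[, "v_q1"] == 1), 1:3)
  expect_equal(which(t1[, "v_q3"] == 1), 7:9)

  v <- c(rep(0, 60), runif(40, 1, 2))
  t2 <- tercile_encode(v, "w")
  expect_true(all(t2[v == 0, "w_q1"] == 1)) # ties all in q1
  expect_true(all(rowSums(t2) == 1))

  set.seed(1)
  t3 <- tercile_encode(runif(300), "u")
  expect_true(all(abs(colSums(t3) - 100) <= 2))
  expect_true(all(rowSums(t3) == 1))

  expect_error(tercile_encode(rep(1, 10)), "constant")
  expect_error(tercile_encode(c(1, 2)), "at least 3")
})
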