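test_that("presets encode the documented strata shares and effect structure", {
  expect_equal(unname(synth_preset("pkh2009")$strata_probs),
               c(0.398, 0.096, 0.506))
  expect_equal(unname(synth_preset("pkh2013")$strata_probs),
               c(0.344, 0.137, 0.519))
  hom <- synth_preset("homogeneous")
  expect_length(hom$tau$coef, 0)
  expect_equal(hom$tau$intercept, 0.2)
  pb <- synth_preset("planted_binary")
  expect_equal(pb$tau$coef, c(x1 = 0.4))
  expect_error(synth_preset("nope"))
})

test_that("config validation catches bad strata, covariates and coefficients", {
  expect_error(synth_config(100, strata_probs = c(0.5, 0.2, 0.2)),
               "summing to 1")
  expect_error(synth_config(100, tau = list(intercept = 0, coef = c(zz = 1))),
               "undeclared")
  expect_error(synth_config(0), "positive")
  expect_error(synth_config(100, p_assign = 1), "p_assign")
})

test_that("degenerate strata designs produce the implied treatment rule", {
  all_comp <- synth_generate(synth_config(1000, seed = 3))
  expect_identical(all_comp$data$d, all_comp$data$z)
  all_at <- synth_generate(synth_config(500, strata_probs = c(0, 1, 0), seed = 3))
  expect_true(all(all_at$data$d == 1))
})

test_that("monotonicity holds by construction", {
  ds <- synth_generate(synth_preset("pkh2013", n = 3000, seed = 11))
  d <- ds$data$d; z <- ds$data$z; s <- ds$truth$stratum
  expect_equal(sum(d > z), sum(s == "always" & z == 0))
  expect_true(all(s[d < z] == "never"))
})

test_that("empirical complier share matches the configured probability", {
  ds <- synth_generate(synth_preset("pkh2009", n = 20000, seed = 5))
  share <- mean(ds$truth$stratum == "complier")
  expect_lt(abs(share - 0.398), 0.01)
  # first-stage difference converges to the complier share
  d <- ds$data$d; z <- ds$data$z
  fs <- mean(d[z == 1]) - mean(d[z == 0])
  se <- sqrt(var(d[z == 1]) / sum(z == 1) + var(d[z == 0]) / sum(z == 0))
  expect_lt(abs(fs - 0.398), 3 * se)
})

test_that("the seed fully determines the dataset", {
  a <- synth_generate(synth_preset("pkh2009", n = 500, seed = 9))
  b <- synth_generate(synth_preset("pkh2009", n = 500, seed = 9))
  c <- synth_generate(synth_preset("pkh2009", n = 500, seed = 10))
  expect_identical(a$data$y, b$data$y)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$data$y, c$data$y))
})

test_that("exclusion restriction: resampling assignment leaves potential outcomes fixed", {
  base <- synth_preset("pkh2009", n = 800, seed = 21)
  alt <- base; alt$p_assign <- 0.8
  a <- synth_generate(base); b <- synth_generate(alt)
  expect_identical(a$truth$y0, b$truth$y0)
  expect_identical(a$truth$y1, b$truth$y1)
  expect_identical(a$truth$stratum, b$truth$stratum)
  expect_false(identical(a$data$z, b$data$z))
})

test_that("true_late returns the complier-average probability difference", {
  hom <- synth_generate(synth_preset("homogeneous", n = 2000, seed = 2))
  expect_equal(true_late(hom), 0.2) # no clipping in this design
  pb <- synth_generate(synth_preset("planted_binary", n = 4000, seed = 2))
  # oracle: direct average of the stored ground truth over complier rows
  oracle <- mean(pb$truth$true_tau[pb$truth$stratum == "complier"])
  expect_equal(true_late(pb), oracle)
  expect_lt(abs(true_late(pb) - 0.2), 0.03)
  nt <- synth_generate(synth_config(200, strata_probs = c(0, 0, 1), seed = 1))
  expect_error(true_late(nt), "no compliers")
})

test_that("cluster-level assignment is constant within clusters", {
  cfg <- synth_config(600, n_clusters = 30,
                      strata_probs = c(0.4, 0.1, 0.5), seed = 4)
  ds <- synth_generate(cfg)
  z_by_cl <- tapply(ds$data$z, ds$data$cluster, function(v) length(unique(v)))
  expect_true(all(z_by_cl == 1))
})

test_that("written trials round-trip through read_trial", {
  sd_ <- synth_generate(synth_preset("pkh2009", n = 300, seed = 8))
  path <- tempfile(fileext = ".tsv")
  write_trial(sd_, path)
  expect_true(file.exists(paste0(path, ".truth")))
  ds2 <- read_trial(path, supply_tags = sd_$data$supply_tags)
  expect_equal(ds2$y, sd_$data$y)
  expect_equal(ds2$d, sd_$data$d)
  expect_equal(ds2$z, sd_$data$z)
  expect_equal(ds2$X, sd_$data$X)
})

test_that("flat key-value config files reproduce the in-code configuration", {
  path <- tempfile(fileext = ".cfg")
  writeLines(c("# planted-modifier design",
               "n = 400", "p_assign = 0.5",
               "strata_probs = 0.398,0.096,0.506",
               "covariate_x1 = binary:0.5",
               "covariate_supply = tercile",
               "tau_intercept = 0", "tau_x1 = 0.4",
               "m_intercept = 0.4", "m_supply_q3 = 0.05",
               "supply_tags = supply_q1,supply_q2,supply_q3",
               "seed = 13"), path)
  cfg <- read_synth_config(path)
  ref <- synth_config(400, strata_probs = c(0.398, 0.096, 0.506),
                      covariates = list(x1 = list(kind = "binary", prob = 0.5),
                                        supply = list(kind = "tercile")),
                      tau = list(intercept = 0, coef = c(x1 = 0.4)),
                      baseline = list(intercept = 0.4,
                                      coef = c(supply_q3 = 0.05)),
                      supply_tags = paste0("supply_q", 1:3), seed = 13)
  expect_identical(synth_generate(cfg)$data$y, synth_generate(ref)$data$y)
  expect_identical(cfg$supply_tags, ref$supply_tags)

  p2 <- tempfile(); writeLines(c("preset = pkh2013", "n = 200", "seed = 3"), p2)
  expect_identical(synth_generate(read_synth_config(p2))$truth,
                   synth_generate(synth_preset("pkh2013", 200, 3))$truth)
  p3 <- tempfile(); writeLines("n 400", p3)
  expect_error(read_synth_config(p3), "malformed")
})

test_that("continuous-outcome mode uses additive noise", {
  cfg <- synth_config(500, noise_sd = 0.1, seed = 6)
  ds <- synth_generate(cfg)
  expect_false(is_binary <- all(ds$data$y %in% c(0, 1)))
  expect_equal(ds$truth$y1 - ds$truth$y0, rep(0.2, 500))
})
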