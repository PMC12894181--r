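# Shared fixtures and small parameter sets used across the suite.

quick_params <- function(num_trees = 50, seed = 1, ...) {
  forest_params(num_trees = num_trees, seed = seed, ...)
}

# Grouped reconstruction of a two-arm encouragement design from printed
# marginals: arm-level outcome means and enrolment counts.
grouped_trial <- function(n0, n_enrolled0, ybar0, n1, n_enrolled1, ybar1) {
  z <- c(rep(0L, n0), rep(1L, n1))
  d <- c(rep(1L, n_enrolled0), rep(0L, n0 - n_enrolled0),
         rep(1L, n_enrolled1), rep(0L, n1 - n_enrolled1))
  y <- c(rep(ybar0, n0), rep(ybar1, n1))
  trial_dataset(y, d, z, X = matrix(1, n0 + n1, 1,
                                    dimnames = list(NULL, "const")),
                allow_nonbinary_y = TRUE)
}

# Fake nuisance/compliance containers for hand-arithmetic fixtures.
fake_nuisances <- function(m_hat, e_hat, g_hat) {
  structure(list(m_hat = m_hat, e_hat = e_hat, g_hat = g_hat,
                 clipped = list(e = integer(), g = integer())),
            class = "nuisances")
}

fake_compliance <- function(delta_hat, clipped = integer()) {
  structure(list(delta_hat = delta_hat, raw = delta_hat, clipped = clipped,
                 n_negative = 0L),
            class = "compliance_scores")
}

# Brute-force depth-2 policy search: enumerate every (root, left, right)
# variable assignment and all 16 leaf-action patterns.
brute_force_depth2 <- function(X, gamma) {
  p <- ncol(X)
  best <- -Inf
  for (k1 in seq_len(p)) for (k2 in seq_len(p)) for (k3 in seq_len(p)) {
    hi <- X[, k1] > 0.5
    for (a in 0:15) {
      acts <- as.integer(intToBits(a))[1:4]
      pi_ <- ifelse(!hi,
                    ifelse(X[, k2] <= 0.5, acts[1], acts[2]),
                    ifelse(X[, k3] <= 0.5, acts[3], acts[4]))
      best <- max(best, mean((2 * pi_ - 1) * gamma))
    }
  }
  best
}

random_policy_instance <- function(seed, n = 50, p = 4) {
  set.seed(seed)
  list(X = matrix(rbinom(n * p, 1, 0.5), n, p,
                  dimnames = list(NULL, paste0("v", seq_len(p)))),
       gamma = rnorm(n))
}
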