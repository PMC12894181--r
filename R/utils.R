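# Internal helpers shared across modules.

clip01 <- function(x, lo = 0.01, hi = 0.99) pmin(pmax(x, lo), hi)

is_binary <- function(x) all(x %in% c(0, 1))

# Derive a bounded integer sub-seed from a base seed and a stream index.
# Keeps every derived seed strictly below 2^31 - 1.
sub_seed <- function(seed, k) {
  (abs(as.double(seed)) + k * 1000003) %% (2^31 - 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

# Population-covariance Wald ratio shared by leaf_wald() and the weighted
# prediction path.
cov_n <- function(a, b) mean(a * b) - mean(a) * mean(b)
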