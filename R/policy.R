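#' Learn an optimal depth-limited policy tree by exhaustive search
#'
#' Finds a binary decision tree of depth at most `depth` over 0/1
#' indicator covariates that maximises the empirical value
#' `A_n(pi) = (1/N) sum_i (2 pi(X_i) - 1) Gamma_i` over the doubly robust
#' scores. The search is exact, not greedy: every assignment of split
#' variables to internal nodes is considered (thresholds are fixed at 0.5,
#' which is exhaustive for indicators), and each leaf takes the action
#' with the larger score sum. Ties break lexicographically — lowest
#' covariate index first, then not-treat before treat — so results are
#' deterministic. Sibling leaves may carry equal actions, which is how
#' shallower trees are represented; depth-`d` search therefore dominates
#' all depths below `d`.
#'
#' @param X Matrix of 0/1 indicator covariates (run [tercile_encode()]
#'   first for continuous columns).
#' @param gamma A `dr_scores` object or numeric score vector.
#' @param depth Tree depth, 1 to 3.
#' @return A `policy_tree`: nested nodes
#'   `list(var, index, left, right)` / leaves `list(action)`, plus the
#'   achieved value and search statistics.
#' @export
learn_policy_tree <- function(X, gamma, depth = 2) {
  g <- if (is.data.frame(gamma)) gamma$gamma else as.numeric(gamma)
  X <- as_feature_matrix(X)
  if (!all(X %in% c(0, 1)))
    stopf("learn_policy_tree: covariates must be 0/1 indicators; encode continuous columns with tercile_encode() first")
  if (!depth %in% 1:3) stopf("learn_policy_tree: depth must be 1, 2 or 3")
  if (length(g) != nrow(X)) stopf("learn_policy_tree: gamma and X not aligned")
  p <- ncol(X)
  nms <- colnames(X)
  n_eval <- 0L

  leaf <- function(s) list(action = if (s > 0) 1L else 0L)

  # depth-1 subproblem, vectorised over all candidate split variables
  solve1 <- function(idx) {
    s <- sum(g[idx])
    if (length(idx) == 0)
      return(list(value = 0, node = list(var = nms[1], index = 1L,
                                         left = leaf(0), right = leaf(0))))
    s1 <- as.vector(crossprod(X[idx, , drop = FALSE], g[idx]))
    s0 <- s - s1
    vals <- abs(s0) + abs(s1)
    n_eval <<- n_eval + p
    k <- which.max(vals) # first maximum = lowest covariate index
    list(value = vals[k],
         node = list(var = nms[k], index = as.integer(k),
                     left = leaf(s0[k]), right = leaf(s1[k])))
  }

  solve_d <- function(idx, d) {
    if (d == 1) return(solve1(idx))
    best_val <- -Inf
    best <- NULL
    xk_all <- X[idx, , drop = FALSE]
    for (k in seq_len(p)) {
      lo <- idx[xk_all[, k] <= 0.5]
      hi <- idx[xk_all[, k] > 0.5]
      rl <- solve_d(lo, d - 1)
      rr <- solve_d(hi, d - 1)
      v <- rl$value + rr$value
      n_eval <<- n_eval + 1L
      if (v > best_val) {
        best_val <- v
        best <- list(var = nms[k], index = as.integer(k),
                     left = rl$node, right = rr$node)
      }
    }
    list(value = best_val, node = best)
  }

  res <- solve_d(seq_len(nrow(X)), depth)
  structure(list(tree = res$node, depth = depth,
                 value = res$value / nrow(X), n = nrow(X),
                 feature_names = nms,
                 search = list(nodes_evaluated = n_eval)),
            class = "policy_tree")
}

#' @export
print.policy_tree <- function(x, ...) {
  cat(sprintf("policy tree (depth <= %d), value = %.4f, n = %d\n",
              x$depth, x$value, x$n))
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (!is.null(node$action)) {
      cat(pad, if (node$action == 1) "-> treat" else "-> do not treat", "\n",
          sep = "")
    } else {
      cat(pad, node$var, " <= 0.5?\n", sep = "")
      show(node$left, indent + 1)
      show(node$right, indent + 1)
    }
  }
  show(x$tree, 1)
  invisible(x)
}

#' Route units through a policy tree
#'
#' @param tree A `policy_tree`.
#' @param X Covariate matrix containing the tree's split variables.
#' @return Integer 0/1 action vector.
#' @export
apply_policy <- function(tree, X) {
  stopifnot(inherits(tree, "policy_tree"))
  X <- as_feature_matrix(X)
  need <- collect_vars(tree$tree)
  miss <- setdiff(need, colnames(X))
  if (length(miss)) stopf("apply_policy: missing covariate(s): %s",
                          paste(miss, collapse = ", "))
  a <- integer(nrow(X))
  route <- function(node, idx) {
    if (length(idx) == 0) return(invisible())
    if (!is.null(node$action)) {
      a[idx] <<- node$action
    } else {
      lo <- X[idx, node$var] <= 0.5
      route(node$left, idx[lo])
      route(node$right, idx[!lo])
    }
  }
  route(tree$tree, seq_len(nrow(X)))
  a
}

collect_vars <- function(node) {
  if (!is.null(node$action)) return(character())
  unique(c(node$var, collect_vars(node$left), collect_vars(node$right)))
}

#' Empirical value of a policy
#'
#' Plug-in value `A_n(pi) = (1/N) sum (2 pi(X_i) - 1) Gamma_i`, with the
#' constant baselines treat-all (`mean(Gamma)`) and treat-none
#' (`-mean(Gamma)`) and the advantage over the best constant policy.
#'
#' @param tree A `policy_tree`.
#' @param X Covariate matrix.
#' @param gamma Scores.
#' @return A `policy_value` list.
#' @export
policy_value <- function(tree, X, gamma) {
  g <- if (is.data.frame(gamma)) gamma$gamma else as.numeric(gamma)
  a <- apply_policy(tree, X)
  v <- mean((2 * a - 1) * g)
  treat_all <- mean(g)
  structure(list(value = v, treat_all = treat_all, treat_none = -treat_all,
                 advantage = v - max(treat_all, -treat_all),
                 treated_share = mean(a)),
            class = "policy_value")
}

#' @export
print.policy_value <- function(x, ...) {
  cat(sprintf("policy value %.4f (treat-all %.4f, treat-none %.4f, advantage %.4f)\n",
              x$value, x$treat_all, x$treat_none, x$advantage))
  invisible(x)
}

#' Serialise a policy tree to nested-record JSON
#'
#' @param tree A `policy_tree`.
#' @param path Output path; `NULL` returns the JSON string.
#' @export
policy_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "policy_tree"))
  enc <- function(node) {
    if (!is.null(node$action))
      return(list(action = node$action))
    list(variable = node$var, threshold = 0.5,
         left = enc(node$left), right = enc(node$right))
  }
  obj <- list(depth = tree$depth, value = tree$value, n = tree$n,
              tree = enc(tree$tree))
  js <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
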