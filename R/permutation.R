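# Two-group permutation machinery shared by the differential screens.
#
# Statistic: absolute difference of group means. Exhaustive enumeration of
# label arrangements is used whenever choose(n, n1) is small enough; the
# exhaustive p is the exact fraction of arrangements with a statistic at
# least as extreme as the observed one (ties count as extreme, and the
# observed arrangement is among those enumerated, so p > 0). Sampled mode
# uses the (1 + #extreme) / (1 + B) convention, which can never report 0.

#' Two-group permutation test on the absolute difference of means
#'
#' @param x,y Numeric vectors for the two groups (each of length >= 2).
#' @param n_perm Number of sampled permutations when exhaustive enumeration
#'   is infeasible.
#' @param seed Seed for sampled mode (ignored in exhaustive mode).
#' @param exhaustive_max Enumerate all label arrangements when their number
#'   `choose(n, n1)` does not exceed this.
#' @return List: `p`, `statistic` (observed |mean(x) - mean(y)|),
#'   `n_perm` (arrangements evaluated), `exhaustive`.
#' @export
permutation_group_test <- function(x, y, n_perm = 4999, seed = 1,
                                   exhaustive_max = 20000) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  v <- matrix(c(x, y), ncol = 1)
  g1 <- seq_along(x)
  res <- perm_test_matrix(v, g1, n1 = length(x), n_perm = n_perm, seed = seed,
                          exhaustive_max = exhaustive_max)
  list(p = res$p[1], statistic = res$statistic[1], n_perm = res$n_perm,
       exhaustive = res$exhaustive)
}

# Vectorized engine: V is an n x S matrix of per-sample values for S
# features; idx1 are the row indices of group 1. Returns per-feature p.
perm_test_matrix <- function(V, idx1, n1 = length(idx1), n_perm = 4999,
                             seed = 1, exhaustive_max = 20000) {
  V <- as.matrix(V)
  n <- nrow(V)
  n2 <- n - n1
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  tot <- colSums(V)
  obs_s1 <- colSums(V[idx1, , drop = FALSE])
  obs <- abs(obs_s1 / n1 - (tot - obs_s1) / n2)
  K <- choose(n, n1)
  tol <- 1e-12
  if (K <= exhaustive_max) {
    combs <- utils::combn(n, n1)
    M <- matrix(0, n, ncol(combs))
    M[cbind(as.vector(combs), rep(seq_len(ncol(combs)), each = n1))] <- 1
    s1 <- crossprod(M, V)                     # K x S group-1 sums
    stat <- abs(s1 / n1 - sweep(-s1, 2, tot, "+") / n2)
    extreme <- stat >= rep(obs, each = nrow(stat)) - tol
    p <- colMeans(extreme)
    list(p = p, statistic = obs, n_perm = ncol(combs), exhaustive = TRUE)
  } else {
    set.seed(stage_seed(seed, "perm"))
    M <- vapply(seq_len(n_perm), function(b) {
      z <- numeric(n); z[sample.int(n, n1)] <- 1; z
    }, numeric(n))                            # n x B indicator matrix
    s1 <- crossprod(M, V)                     # B x S group-1 sums
    stat <- abs(s1 / n1 - sweep(-s1, 2, tot, "+") / n2)
    cnt <- colSums(stat >= rep(obs, each = n_perm) - tol)
    list(p = (1 + cnt) / (1 + n_perm), statistic = obs, n_perm = n_perm,
         exhaustive = FALSE)
  }
}

#' Benjamini-Hochberg adjusted p-values (step-up FDR)
#'
#' Validated wrapper around the standard step-up adjustment: `q_(i) =
#' min_{j >= i} min(1, m p_(j) / j)` over the sorted p-values.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Vector of adjusted q-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
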