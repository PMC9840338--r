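# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive brute-force computations, independent of the package's code paths.

tiny_cohort <- function(S = 30, n_ctl = 5, n_cel = 4, age = 2.5,
                        depth = 3000, seed = 7, ...) {
  gs <- stats::setNames(list(c(control = n_ctl, celiac = n_cel)),
                        as.character(age))
  simulate_cohort(sim_config(n_taxa = S, group_sizes = gs,
                             depth_mean = depth, seed = seed, ...))
}

# direct step-up BH adjustment
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive two-group permutation p for |difference of means|
perm_oracle <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  obs <- abs(mean(x) - mean(y))
  combs <- utils::combn(length(v), n1)
  stats <- apply(combs, 2, function(i) abs(mean(v[i]) - mean(v[-i])))
  mean(stats >= obs - 1e-12)
}

# brute-force PERMANOVA p by label enumeration, F from vegan (independent)
permanova_oracle <- function(d, groups) {
  stopifnot(requireNamespace("vegan", quietly = TRUE))
  f_of <- function(g) {
    df <- data.frame(g = factor(g))
    suppressMessages(as.numeric(
      vegan::adonis2(stats::as.dist(d) ~ g, data = df, permutations = 1)$F[1]))
  }
  lv <- unique(groups)
  n1 <- sum(groups == lv[1])
  n <- length(groups)
  f_obs <- f_of(groups)
  combs <- utils::combn(n, n1)
  f_perm <- apply(combs, 2, function(i) {
    g <- rep(lv[2], n); g[i] <- lv[1]; f_of(g)
  })
  list(F = f_obs, p = mean(f_perm >= f_obs - 1e-8))
}

# closed-form group ICI at infinite depth, perfect sort, no pseudocount
ici_closed_form <- function(p, theta) {
  (theta / (1 - theta)) * (sum(p * (1 - theta)) / sum(p * theta))
}

# the targeting benchmark is used by two acceptance properties; run it once
bench_cache <- new.env()
cached_benchmark <- function() {
  if (is.null(bench_cache$b))
    bench_cache$b <- targeting_benchmark(n_seeds = 20, seed = 1)
  bench_cache$b
}

write_tsv_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
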