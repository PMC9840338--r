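# Community-level statistics: observed richness, Bray-Curtis dissimilarity,
# PERMANOVA on a distance matrix, PCA ordination, and one-/two-way ANOVA.

#' Observed richness per sample
#'
#' Number of taxa with a non-zero count in each sample; invariant to count
#' scaling.
#'
#' @param table A `count_table` (or non-negative matrix).
#' @return Named integer vector, one entry per sample.
#' @export
observed_richness <- function(table) {
  m <- unclass(as.matrix(table))
  colSums(m > 0)
}

#' Bray-Curtis dissimilarity between two composition vectors
#'
#' `BC = 1 - 2 sum(min(x, y)) / (sum(x) + sum(y))`; 0 for identical
#' vectors, 1 for disjoint supports.
#'
#' @param x,y Equal-length non-negative vectors, not both all-zero.
#' @return Dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors must have equal length", call. = FALSE)
  if (any(x < 0) || any(y < 0))
    stop("Bray-Curtis requires non-negative vectors", call. = FALSE)
  sx <- sum(x); sy <- sum(y)
  if (sx + sy == 0)
    stop("Bray-Curtis is undefined for two all-zero vectors", call. = FALSE)
  1 - 2 * sum(pmin(x, y)) / (sx + sy)
}

#' Pairwise Bray-Curtis distance matrix over samples
#'
#' Computed on per-sample relative abundances by default, making the
#' distances invariant to sequencing depth; set `relabund = FALSE` to use
#' raw counts.
#'
#' @param table A `count_table`.
#' @param relabund Normalize columns to proportions first (default TRUE).
#' @return Symmetric matrix of class `distance_matrix` with zero diagonal.
#' @export
bray_curtis_matrix <- function(table, relabund = TRUE) {
  m <- unclass(as.matrix(table))
  if (relabund) m <- relative_abundance(m, pseudocount = 0)
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- bray_curtis(m[, i], m[, j])
    }
  }
  class(d) <- c("distance_matrix", "matrix", "array")
  d
}

# Sum-of-squares partition of a distance matrix for given group labels:
# SST = sum of squared distances over all pairs / n, SSW summed within
# groups / group size (Anderson's pseudo-F construction).
permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  sst <- sum(d2) / (2 * n)
  ssw <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    ssw <- ssw + sum(d2[i, i]) / (2 * length(i))
  }
  c(sst = sst, ssw = ssw)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the squared inter-sample distances into among- and
#' within-group sums of squares and forms the pseudo-F statistic
#' `(SSA / (a - 1)) / (SSW / (n - a))`. The p-value is obtained by
#' permuting group labels; for two groups, all `choose(n, n1)` label
#' arrangements are enumerated when feasible (ties count as extreme, so
#' identical point sets give p = 1), otherwise labels are resampled with
#' the (1 + #extreme) / (1 + B) convention.
#'
#' @param d A `distance_matrix` (or symmetric matrix with zero diagonal).
#' @param groups Group labels aligned with the rows of `d` (>= 2 groups,
#'   each with >= 2 samples).
#' @param n_perm Sampled permutations when enumeration is infeasible.
#' @param seed Seed for sampled mode.
#' @param exhaustive_max Cap on enumerated arrangements (two-group designs).
#' @return List of class `permanova_result`: `pseudo_F`, `R2`, `p`,
#'   `n_perm`, `exhaustive`, `seed`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1,
                      exhaustive_max = 20000) {
  d <- unclass(as.matrix(d))
  n <- nrow(d)
  if (length(groups) != n)
    stop("group labels must align with the distance matrix", call. = FALSE)
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("PERMANOVA needs >= 2 groups with >= 2 samples each", call. = FALSE)
  a <- length(sizes)
  d2 <- d^2
  ss <- permanova_ss(d2, groups)
  ssa <- ss["sst"] - ss["ssw"]
  f_obs <- (ssa / (a - 1)) / (ss["ssw"] / (n - a))
  f_of <- function(g) {
    s <- permanova_ss(d2, g)
    ((s["sst"] - s["ssw"]) / (a - 1)) / (s["ssw"] / (n - a))
  }
  tol <- 1e-12
  if (a == 2 && choose(n, sizes[1]) <= exhaustive_max) {
    lv <- names(sizes)
    combs <- utils::combn(n, sizes[1])
    f_perm <- apply(combs, 2, function(i) {
      g <- rep(lv[2], n); g[i] <- lv[1]; f_of(g)
    })
    p <- mean(f_perm >= f_obs - tol)
    n_used <- ncol(combs); exhaustive <- TRUE
  } else {
    set.seed(stage_seed(seed, "permanova"))
    cnt <- 0
    for (b in seq_len(n_perm)) {
      if (f_of(sample(groups)) >= f_obs - tol) cnt <- cnt + 1
    }
    p <- (1 + cnt) / (1 + n_perm)
    n_used <- n_perm; exhaustive <- FALSE
  }
  structure(list(pseudo_F = unname(f_obs), R2 = unname(ssa / ss["sst"]),
                 p = p, n_perm = n_used, exhaustive = exhaustive, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%s, %d permutations)\n",
              x$pseudo_F, x$R2, x$p,
              if (x$exhaustive) "exhaustive" else "sampled", x$n_perm))
  invisible(x)
}

#' PCA ordination of samples
#'
#' Column-centered, unscaled principal component decomposition of the
#' sample-by-taxon relative abundance matrix. A Hellinger (square-root
#' proportion) transform is available for abundance data.
#'
#' @param table A `count_table`, or a samples-in-columns numeric matrix.
#' @param n_components Number of axes to return.
#' @param relabund Convert columns to proportions first.
#' @param hellinger Apply the Hellinger transform (square root of
#'   proportions) before centering.
#' @return List: `scores` (samples x components), `explained`
#'   (per-component fraction of total variance, non-increasing),
#'   `center`, `rotation`.
#' @export
pca_ordination <- function(table, n_components = 2, relabund = TRUE,
                           hellinger = FALSE) {
  m <- unclass(as.matrix(table))
  if (relabund) m <- relative_abundance(m, pseudocount = 0)
  if (hellinger) m <- sqrt(m)
  x <- t(m)                                   # samples x taxa
  if (nrow(x) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  if (n_components > min(dim(x)))
    stop("n_components exceeds matrix rank bound min(n_samples, n_taxa)",
         call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = (ev / sum(ev))[seq_len(k)],
       center = pc$center,
       rotation = pc$rotation[, seq_len(k), drop = FALSE])
}

#' One-way ANOVA
#'
#' Classical F-test for equality of group means (used for alpha-diversity
#' comparisons). With two groups the F statistic equals the squared pooled
#' two-sample t statistic.
#'
#' @param values Numeric response.
#' @param group Factor with >= 2 levels.
#' @return Data frame with `term`, `F`, `p`.
#' @export
anova_oneway <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups", call. = FALSE)
  a <- stats::anova(stats::lm(values ~ group))
  data.frame(term = "group", F = a$`F value`[1], p = a$`Pr(>F)`[1])
}

#' Two-way ANOVA with Type II sums of squares
#'
#' Main effects and interaction for an (possibly unbalanced) two-factor
#' design, e.g. group x age for flow-cytometry IgA+ fractions. Type II sums
#' of squares are robust to imbalance in cell sizes.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Factors with >= 2 levels; every cell of the
#'   crossed design must contain >= 2 observations.
#' @return Data frame with one row per term (`a`, `b`, `a:b`): `F`, `p`.
#' @export
anova_twoway <- function(values, factor_a, factor_b) {
  a <- factor(factor_a); b <- factor(factor_b)
  if (nlevels(a) < 2 || nlevels(b) < 2)
    stop("both factors need >= 2 levels", call. = FALSE)
  cells <- table(a, b)
  if (any(cells < 2)) {
    bad <- which(cells < 2, arr.ind = TRUE)[1, ]
    stop(sprintf("design cell (%s, %s) has fewer than 2 observations",
                 levels(a)[bad[1]], levels(b)[bad[2]]), call. = FALSE)
  }
  fit <- stats::lm(values ~ a * b)
  tab <- car::Anova(fit, type = 2)
  terms <- c("a", "b", "a:b")
  data.frame(term = terms,
             F = tab[terms, "F value"],
             p = tab[terms, "Pr(>F)"])
}
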