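test_that("relative abundance normalizes columns with optional pseudocount", {
  m <- matrix(c(10, 30, 60), 3, 1, dimnames = list(paste0("t", 1:3), "S1"))
  expect_equal(unname(relative_abundance(m, 0)[, 1]), c(0.1, 0.3, 0.6))
  m2 <- matrix(c(0, 9), 2, 1, dimnames = list(c("a", "b"), "S1"))
  expect_equal(unname(relative_abundance(m2, 1)[, 1]), c(1 / 11, 10 / 11))
  expect_error(relative_abundance(matrix(0, 2, 1), 0), "degenerate")
  expect_equal(colSums(relative_abundance(matrix(rpois(20, 5), 4, 5) + 1, 1)),
               rep(1, 5), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("per-taxon ICI is the IgA+/IgA- relative abundance ratio", {
  expect_equal(ici_per_taxon(c(0.3, 0.7), c(0.3, 0.7)), c(1, 1))
  expect_equal(ici_per_taxon(0.2, 0.1), 2.0)
  expect_error(ici_per_taxon(c(0.1), c(0)), "pseudocount")
  # perfect-sort expected compositions follow the closed form
  q <- expected_sorted_compositions(c(0.5, 0.5), c(0.8, 0.2), 0)
  expect_equal(ici_per_taxon(q$pos, q$neg), c(4.0, 0.25), tolerance = 1e-12)
  expect_equal(ici_per_taxon(q$pos, q$neg),
               ici_closed_form(c(0.5, 0.5), c(0.8, 0.2)), tolerance = 1e-12)
})

test_that("expected ICI increases strictly with coating probability", {
  set.seed(3)
  p <- prop.table(rgamma(10, 2))
  th <- runif(10, 0.1, 0.9)
  grid <- seq(0.05, 0.95, by = 0.05)
  ici_t <- vapply(grid, function(v) {
    th2 <- th; th2[4] <- v
    q <- expected_sorted_compositions(p, th2, 0)
    ici_per_taxon(q$pos, q$neg)[4]
  }, numeric(1))
  expect_true(all(diff(ici_t) > 0))
})

test_that("group ICI reduces to the single-subject ICI and is idempotent over clones", {
  sim <- tiny_cohort(S = 20, n_ctl = 1, n_cel = 1, seed = 13, depth = 1e4)
  md <- sim$metadata
  rel <- relative_abundance(sim$counts, pseudocount = 1)
  pos <- md$sample_id[md$group == "control" & md$fraction == "igapos"]
  neg <- md$sample_id[md$group == "control" & md$fraction == "iganeg"]
  manual <- ici_per_taxon(rel[, pos], rel[, neg])
  g1 <- group_ici(sim$counts, md, "control", 2.5)
  expect_equal(unname(g1), unname(manual), tolerance = 1e-12)
  expect_equal(unname(group_ici(sim$counts, md, "control", 2.5,
                                method = "subject_median")),
               unname(manual), tolerance = 1e-12)
  # duplicating a subject's samples leaves the pooled-mean estimator unchanged
  cnt2 <- cbind(unclass(sim$counts),
                unclass(sim$counts)[, c(pos, neg,
                                        md$sample_id[md$group == "control" &
                                                       md$fraction == "presort"])])
  colnames(cnt2) <- c(colnames(sim$counts), "dup_pos", "dup_neg", "dup_pre")
  md2 <- rbind(as.data.frame(md),
               data.frame(sample_id = c("dup_pos", "dup_neg", "dup_pre"),
                          subject_id = "dup", group = "control", age = 2.5,
                          fraction = c("igapos", "iganeg", "presort")))
  g2 <- group_ici(count_table(cnt2), md2, "control", 2.5)
  expect_equal(unname(g2), unname(g1), tolerance = 1e-12)
  expect_error(group_ici(sim$counts, md, "celiac", 5), "no sorted")
})

test_that("ICI is invariant to per-sample count scaling", {
  # even community at high depth so every cell count dwarfs the pseudocount
  sim <- tiny_cohort(S = 25, n_ctl = 3, n_cel = 2, seed = 17, depth = 1e6,
                     base_log_sd = 0.3)
  cnt <- unclass(sim$counts)
  scaled <- cnt
  scaled[, 2] <- scaled[, 2] * 7L
  scaled[, 5] <- scaled[, 5] * 3L
  # exact invariance at pseudocount 0
  g0 <- group_ici(count_table(cnt), sim$metadata, "control", 2.5, pseudocount = 0)
  g0s <- group_ici(count_table(scaled), sim$metadata, "control", 2.5, pseudocount = 0)
  expect_equal(unname(g0), unname(g0s), tolerance = 1e-14)
  # near-invariance with pseudocount 1: perturbation is O(pseudocount/depth)
  g1 <- group_ici(count_table(cnt), sim$metadata, "control", 2.5)
  g1s <- group_ici(count_table(scaled), sim$metadata, "control", 2.5)
  expect_equal(unname(g1), unname(g1s), tolerance = 1e-4)
})

test_that("retention rule keeps taxa coated in either group and discordant ones", {
  flags <- retention_filter(c(0.5, 2), c(0.8, 3))
  expect_equal(flags$retained, c(FALSE, TRUE))
  expect_equal(flags$discordant, c(FALSE, FALSE))
  disc <- retention_filter(c(0.5, 3), c(2.0, 0.4))
  expect_true(all(disc$retained) && all(disc$discordant))
  # boundary: exactly 1 is not "lower than 1", hence retained
  expect_true(retention_filter(1.0, 1.0)$retained)
  expect_false(retention_filter(1.0, 1.0)$discordant)
  expect_false(retention_filter(1.0, 0.5)$retained)
  expect_error(retention_filter(c(1, -2), c(1, 1)), "positive")
})

test_that("row normalization z-scores rows and zeroes constant rows", {
  z <- normalize_rows(matrix(c(2, 8), 1))
  expect_equal(unname(z[1, ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(normalize_rows(matrix(5, 1, 3))[1, ]), c(0, 0, 0))
  set.seed(9)
  m <- matrix(rnorm(40), 8, 5)
  zm <- normalize_rows(m)
  expect_equal(unname(rowMeans(zm)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(zm, 1, sd)), rep(1, 8), tolerance = 1e-12)
})

test_that("high-coater calls use a strict threshold", {
  ici <- c(a = 12, b = 10.0, c = 10.0001, d = 0.2)
  expect_identical(high_coaters(ici), c("a", "c"))
  expect_identical(high_coaters(numeric(0)), character(0))
})

test_that("strongly coated taxa are flagged as high coaters in simulated cohorts", {
  th <- rep(0.1, 30); th[3] <- 0.9
  hits <- vapply(1:10, function(s) {
    sim <- tiny_cohort(S = 30, n_ctl = 16, n_cel = 2, seed = 100 + s,
                       depth = 30471, coating_theta_control = th,
                       coating_theta_celiac = th)
    g <- group_ici(sim$counts, sim$metadata, "control", 2.5)
    g[3] > 10
  }, logical(1))
  # closed-form ICI for theta 0.9 against a 0.1 background is far above 10
  expect_gt(ici_closed_form(rep(1 / 30, 30), th)[3], 10)
  expect_gte(sum(hits), 9)
})

test_that("ici_table assembles flags and a row-normalized heatmap", {
  sim <- tiny_cohort(S = 30, n_ctl = 4, n_cel = 4, seed = 23)
  it <- ici_table(sim$counts, sim$metadata, 2.5, include_abundance = TRUE)
  tab <- it$table
  expect_identical(nrow(tab), 30L)
  expect_equal(tab$retained,
               (pmin(tab$ici_control, tab$ici_celiac) >= 1) | tab$discordant)
  expect_equal(tab$discordant,
               (tab$ici_control < 1 & tab$ici_celiac > 1) |
                 (tab$ici_control > 1 & tab$ici_celiac < 1))
  expect_equal(tab$high_coater_control, tab$ici_control > 10)
  expect_identical(nrow(it$heatmap), sum(tab$retained))
  expect_identical(colnames(it$heatmap),
                   c("ici_control", "ici_celiac", "relabund_control",
                     "relabund_celiac"))
  nonconst <- apply(it$heatmap, 1, sd) > 0
  expect_equal(unname(rowMeans(it$heatmap)), rep(0, nrow(it$heatmap)),
               tolerance = 1e-12)
  expect_equal(unname(apply(it$heatmap, 1, sd)[nonconst]),
               rep(1, sum(nonconst)), tolerance = 1e-12)
})
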