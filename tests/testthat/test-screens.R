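test_that("differential abundance reports signed fold-changes and conjunctive calls", {
  sim <- tiny_cohort(S = 30, n_ctl = 8, n_cel = 8, seed = 41, depth = 20000,
                     subject_conc = 500, effect_taxa = 3, effect_log2fc = 2.5)
  da <- differential_abundance(sim$counts, sim$metadata, "presort", 2.5,
                               seed = 1)
  expect_gt(da$log2fc[3], 0)
  expect_true(all(da$significant == (da$q < 0.05 & da$p < 0.01)))
  # BH step-up compatibility: q is a monotone transform of p after sorting
  o <- order(da$p)
  expect_true(all(diff(da$q[o]) >= -1e-12))
  expect_error(differential_abundance(sim$counts, sim$metadata, "presort", 5),
               "no samples")
})

test_that("swapping group labels negates fold-changes and preserves exhaustive p-values", {
  sim <- tiny_cohort(S = 20, n_ctl = 4, n_cel = 4, seed = 43)
  md_sw <- as.data.frame(sim$metadata)
  md_sw$group <- ifelse(md_sw$group == "control", "celiac", "control")
  a <- differential_abundance(sim$counts, sim$metadata, "presort", 2.5)
  b <- differential_abundance(sim$counts, md_sw, "presort", 2.5)
  expect_true(a$significant[1] %in% c(TRUE, FALSE))  # well-formed
  expect_true(attr(a, "test")$exhaustive)
  expect_equal(b$log2fc, -a$log2fc, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})

test_that("targeting composite requires comparable presort AND differential coating", {
  # strong presort difference, identical coating: never differentially targeted
  th <- rep(0.15, 25)
  sim <- tiny_cohort(S = 25, n_ctl = 8, n_cel = 8, seed = 47, depth = 30471,
                     subject_conc = 500, effect_taxa = 2, effect_log2fc = 4,
                     coating_theta_control = th, coating_theta_celiac = th)
  tg <- differential_targeting(sim$counts, sim$metadata, 2.5, seed = 3)
  expect_true(all(tg$differentially_targeted ==
                    (tg$presort_comparable & tg$coating_differential)))
  expect_false(tg$differentially_targeted[2])
  # the planted presort effect is itself detected as non-comparable
  expect_false(tg$presort_comparable[2])
})

test_that("per-subject ICI coating signal is selectable for targeting", {
  th_c <- rep(0.1, 25); th_d <- th_c; th_d[5] <- 0.85
  sim <- tiny_cohort(S = 25, n_ctl = 10, n_cel = 10, seed = 53, depth = 30471,
                     subject_conc = 200,
                     coating_theta_control = th_c, coating_theta_celiac = th_d)
  tg <- differential_targeting(sim$counts, sim$metadata, 2.5,
                               coating_on = "ici", seed = 7)
  expect_identical(attr(tg, "coating_on"), "ici")
  expect_true(tg$differentially_targeted[5])
})

test_that("volcano screen gates on both fold-change and p-value", {
  set.seed(61)
  base <- matrix(rlnorm(40 * 16, 0, 0.3), 40, 16)
  grp <- rep(c("control", "celiac"), each = 8)
  base[1, grp == "celiac"] <- base[1, grp == "celiac"] * 2^1.5  # passes both
  base[2, grp == "celiac"] <- base[2, grp == "celiac"] * 2^1.0  # fails FC gate
  ft <- feature_table(base)
  v <- volcano_screen(ft, grp)
  expect_true(v$volcano_significant[1])
  expect_identical(v$volcano_class[1], "up")
  expect_false(v$volcano_significant[2])
  expect_identical(v$volcano_class[2], "ns")
  expect_true(all(v$volcano_significant ==
                    (abs(v$log2fc) > 1.2 & -log10(v$p) > 0.1)))
  # constant feature: p defined as 1 with a flag
  cons <- base; cons[3, ] <- 5
  expect_warning(v2 <- volcano_screen(feature_table(cons), grp), "constant")
  expect_equal(v2$p[3], 1)
  expect_true(v2$constant_flag[3])
})

test_that("planted 1.92-fold analyte is recovered at the cohort's panel size", {
  est <- vapply(1:30, function(s) {
    sim <- simulate_feature_table(30, c(control = 9, celiac = 7),
                                  effect_features = 4,
                                  effect_log2fc = log2(1.92), seed = 300 + s)
    v <- volcano_screen(sim$features, sim$metadata)
    2^v$log2fc[4]
  }, numeric(1))
  expect_equal(mean(est), 1.92, tolerance = 0.15)
})

test_that("mean-abundance screen filters strictly above the 1% threshold", {
  # deterministic composition: taxa at 0.9%, exactly 1%, and the rest
  depth <- 10000
  prop <- c(0.009, 0.01, 0.481, 0.5)
  m <- matrix(rep(prop * depth, 8), ncol = 8,
              dimnames = list(paste0("a", 1:4), paste0("S", 1:8)))
  md <- data.frame(sample_id = paste0("S", 1:8),
                   subject_id = paste0("sub", 1:8),
                   group = rep(c("control", "celiac"), each = 4),
                   age = 2.5, fraction = "presort")
  tax <- data.frame(taxon_id = paste0("a", 1:4),
                    lineage = paste0("K;P;C;O;F;G", 1:4, ";s"))
  res <- group_mean_relabund_screen(count_table(m), md, tax, "genus", age = 2.5)
  expect_false("G1" %in% res$feature_id)  # 0.9% excluded
  expect_false("G2" %in% res$feature_id)  # exactly 1% excluded (strict >)
  expect_true(all(c("G3", "G4") %in% res$feature_id))
  # nothing passes an impossible filter
  expect_message(
    empty <- group_mean_relabund_screen(count_table(m), md, tax, "genus",
                                        age = 2.5, min_mean_abundance = 0.99),
    "no taxa")
  expect_identical(nrow(empty), 0L)
})

test_that("rank-level null screen stays calibrated at the FDR threshold", {
  set.seed(71)
  rejections <- 0; total <- 0
  for (r in 1:40) {
    m <- matrix(rpois(12 * 10, 200), nrow = 12,
                dimnames = list(sprintf("a%02d", 1:12), paste0("S", 1:10)))
    md <- data.frame(sample_id = paste0("S", 1:10),
                     subject_id = paste0("sub", 1:10),
                     group = rep(c("control", "celiac"), each = 5),
                     age = 2.5, fraction = "presort")
    tax <- data.frame(taxon_id = rownames(m),
                      lineage = paste0("K;P;C;O;F;G", 1:12, ";s"))
    res <- group_mean_relabund_screen(count_table(m), md, tax, "genus",
                                      age = 2.5)
    rejections <- rejections + sum(res$significant)
    total <- total + nrow(res)
  }
  # q < 0.05 null rejections, allowing two Monte-Carlo standard errors
  expect_lte(rejections / total, 0.05 + 2 * sqrt(0.05 * 0.95 / total))
})
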