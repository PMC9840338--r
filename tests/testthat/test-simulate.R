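test_that("expected sorted compositions follow the sorting model", {
  # neutral coating: both pools equal the presort composition
  q <- expected_sorted_compositions(c(0.5, 0.5), c(0.5, 0.5), 0)
  expect_equal(q$pos, c(0.5, 0.5))
  expect_equal(q$neg, c(0.5, 0.5))
  # perfect sort: closed form p*theta / sum(p*theta)
  q2 <- expected_sorted_compositions(c(0.5, 0.5), c(0.8, 0.2), 0)
  expect_equal(q2$pos, c(0.8, 0.2), tolerance = 1e-12)
  expect_equal(q2$neg, c(0.2, 0.8), tolerance = 1e-12)
  # complete mixing: the two pools are indistinguishable
  set.seed(5)
  p <- prop.table(runif(8)); th <- runif(8, 0.05, 0.95)
  q3 <- expected_sorted_compositions(p, th, 0.5)
  expect_equal(q3$pos, q3$neg, tolerance = 1e-12)
  expect_error(expected_sorted_compositions(c(0.6, 0.5), c(0.5, 0.5), 0),
               "sum to 1")
  expect_error(expected_sorted_compositions(c(0.5, 0.5), c(0, 0.5), 0),
               "strictly in")
})

test_that("sorted compositions conserve mass and mix monotonically", {
  set.seed(11)
  for (i in 1:1000) {
    S <- sample(2:20, 1)
    p <- prop.table(rgamma(S, 1))
    th <- runif(S, 1e-3, 1 - 1e-3)
    q <- expected_sorted_compositions(p, th, runif(1, 0, 0.5))
    expect_true(abs(sum(q$pos) - 1) < 1e-12 && abs(sum(q$neg) - 1) < 1e-12)
  }
  # total-variation distance between pools shrinks as impurity grows
  set.seed(12)
  p <- prop.table(rgamma(12, 1)); th <- runif(12, 0.05, 0.95)
  tv <- vapply(seq(0, 0.5, by = 0.05), function(e) {
    q <- expected_sorted_compositions(p, th, e)
    sum(abs(q$pos - q$neg)) / 2
  }, numeric(1))
  expect_true(all(diff(tv) <= 1e-12))
  # coated-fraction-weighted mixture of the pools recovers the presort
  cf <- sum(p * th)
  q0 <- expected_sorted_compositions(p, th, 0)
  expect_equal(cf * q0$pos + (1 - cf) * q0$neg, p, tolerance = 1e-9)
})

test_that("cohort simulation is seed-deterministic and study-scaled", {
  cfg <- sim_config(n_taxa = 40,
                    group_sizes = list("2.5" = c(control = 3, celiac = 3)),
                    seed = 99)
  a <- simulate_cohort(cfg); b <- simulate_cohort(cfg)
  expect_identical(unclass(a$counts), unclass(b$counts))
  expect_identical(as.data.frame(a$metadata), as.data.frame(b$metadata))
  expect_equal(a$truth$ages[["2.5"]]$flow_fraction,
               b$truth$ages[["2.5"]]$flow_fraction)
  # default design: (16+15) + (13+9) subjects, three fractions each
  sim <- simulate_cohort(sim_config(n_taxa = 5, seed = 2))
  expect_identical(ncol(sim$counts), 3L * (31L + 22L))
  expect_identical(sum(sim$metadata$fraction == "presort"), 53L)
  expect_error(sim_config(n_taxa = 0), "n_taxa")
  expect_error(sim_config(impurity = 0.7), "impurity")
})

test_that("neutral coating at high depth leaves sorted fractions near the presort composition", {
  gs <- list("2.5" = c(control = 1, celiac = 1))
  cfg <- sim_config(n_taxa = 25, group_sizes = gs, depth_mean = 1e6,
                    depth_cv = 1e-6, impurity = 0,
                    coating_theta_control = rep(0.5, 25),
                    coating_theta_celiac = rep(0.5, 25),
                    kappa = 1e9, seed = 4)
  sim <- simulate_cohort(cfg)
  md <- sim$metadata
  for (sid in unique(md$subject_id)) {
    p_true <- sim$truth$ages[["2.5"]]$p[, sid]
    for (fr in c("igapos", "iganeg")) {
      cnt <- unclass(sim$counts)[, md$sample_id[md$subject_id == sid &
                                                  md$fraction == fr]]
      tv <- sum(abs(cnt / sum(cnt) - p_true)) / 2
      expect_lt(tv, 0.01)
    }
  }
})

test_that("flow fractions are the composition-coating dot product", {
  sim <- tiny_cohort(S = 15, seed = 21)
  tr <- sim$truth$ages[["2.5"]]
  ff <- simulate_flow_fractions(sim$truth)
  for (i in seq_len(nrow(ff))) {
    sid <- ff$subject_id[i]
    expect_equal(ff$flow_fraction[i],
                 sum(tr$p[, sid] * tr$theta_realized[, sid]),
                 tolerance = 1e-12)
  }
  expect_true(all(ff$flow_fraction > 0 & ff$flow_fraction < 1))
  # constant coating: the coated fraction equals that constant
  cfg <- sim_config(n_taxa = 10,
                    group_sizes = list("5" = c(control = 2, celiac = 2)),
                    coating_theta_control = rep(0.128, 10),
                    coating_theta_celiac = rep(0.128, 10),
                    kappa = 1e9, seed = 5)
  ffc <- simulate_flow_fractions(simulate_cohort(cfg)$truth)
  expect_equal(ffc$flow_fraction, rep(0.128, 4), tolerance = 1e-3)
})

test_that("feature simulation is calibrated under the null and recovers planted fold-changes", {
  # null: t-test rejection rate near alpha
  sim0 <- simulate_feature_table(400, c(control = 20, celiac = 20), seed = 31)
  grp <- sim0$metadata$group
  p <- apply(unclass(sim0$features), 1, function(v)
    t.test(v[grp == "celiac"], v[grp == "control"])$p.value)
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.10)
  # planted 1.92-fold effect: sample fold-change converges to truth
  est <- replicate(20, {
    s <- simulate_feature_table(5, c(control = 150, celiac = 150),
                                effect_features = 1,
                                effect_log2fc = log2(1.92),
                                seed = sample.int(1e6, 1))
    g <- s$metadata$group
    m <- unclass(s$features)
    mean(m[1, g == "celiac"]) / mean(m[1, g == "control"])
  })
  expect_equal(mean(est), 1.92, tolerance = 0.05)
  # determinism
  s1 <- simulate_feature_table(10, seed = 8)
  s2 <- simulate_feature_table(10, seed = 8)
  expect_identical(unclass(s1$features), unclass(s2$features))
})
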