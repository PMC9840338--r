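# Frozen simulation benchmarks used to validate the pipeline's operating
# characteristics. These define the package's reference scenarios; tests and
# the acceptance script both call them so the conditions cannot drift apart.

#' Differential-targeting recovery benchmark
#'
#' The reference scenario for planted-effect recovery: S taxa over a
#' moderately skewed community (log-normal sigma 1), a well-spread
#' background coating spectrum theta ~ U(0.05, 0.9) shared by both groups,
#' and `n_planted` taxa with equal presort abundance but coating 0.8 in
#' celiac vs 0.1 in control; 16 control / 15 celiac subjects sequenced at
#' mean depth 30,471. For each replicate the composite targeting call is run
#' and the Spearman correlation between the true celiac coating
#' probabilities and the estimated celiac group ICI is recorded.
#'
#' @param n_seeds Number of simulation replicates.
#' @param n_taxa Community size.
#' @param n_planted Number of planted coating-effect taxa.
#' @param coating_on Coating signal for the targeting call (default the
#'   per-subject ICI, which pairs the sorted fractions within subject).
#' @param seed Root seed; replicate seeds are derived from it.
#' @return Data frame with one row per replicate: `recovery` (fraction of
#'   planted taxa called differentially targeted), `null_rate` (fraction of
#'   non-planted taxa called), `spearman` (true theta vs group ICI).
#' @export
targeting_benchmark <- function(n_seeds = 20, n_taxa = 100, n_planted = 5,
                                coating_on = "ici", seed = 1) {
  out <- lapply(seq_len(n_seeds), function(i) {
    s <- stage_seed(seed, paste0("bench", i))
    set.seed(stage_seed(s, "scenario_theta"))
    bg <- stats::runif(n_taxa, 0.05, 0.9)
    th_ctl <- bg; th_cel <- bg
    planted <- seq_len(n_planted)
    th_ctl[planted] <- 0.1
    th_cel[planted] <- 0.8
    cfg <- sim_config(n_taxa = n_taxa, base_log_sd = 1,
                      group_sizes = list("2.5" = c(control = 16, celiac = 15)),
                      coating_theta_control = th_ctl,
                      coating_theta_celiac = th_cel,
                      seed = s)
    sim <- simulate_cohort(cfg)
    tg <- differential_targeting(sim$counts, sim$metadata, 2.5,
                                 coating_on = coating_on, seed = s)
    gi <- group_ici(sim$counts, sim$metadata, "celiac", 2.5)
    data.frame(seed = s,
               recovery = mean(tg$differentially_targeted[planted]),
               null_rate = mean(tg$differentially_targeted[-planted]),
               spearman = stats::cor(th_cel, gi, method = "spearman"))
  })
  do.call(rbind, out)
}

#' Null calibration of the presort permutation screen
#'
#' Simulates cohorts with no group effects (identical base composition and
#' coating in both groups) and measures the per-taxon rejection rate of the
#' presort permutation test at nominal level `alpha`. For a calibrated test
#' the rate matches `alpha` up to binomial noise.
#'
#' @param n_cohorts Number of null cohorts.
#' @param n_taxa Taxa per cohort.
#' @param n_per_group Subjects per group (8/8 keeps the label enumeration
#'   exhaustive).
#' @param alpha Nominal level.
#' @param seed Root seed.
#' @return List: `rate` (observed rejection fraction), `n_tests`.
#' @export
null_calibration <- function(n_cohorts = 500, n_taxa = 50, n_per_group = 8,
                             alpha = 0.05, seed = 1) {
  rej <- 0; tot <- 0
  for (i in seq_len(n_cohorts)) {
    s <- stage_seed(seed, paste0("null", i))
    sim <- simulate_cohort(sim_config(
      n_taxa = n_taxa,
      group_sizes = list("2.5" = c(control = n_per_group,
                                   celiac = n_per_group)),
      seed = s))
    da <- differential_abundance(sim$counts, sim$metadata, "presort", 2.5,
                                 seed = s)
    rej <- rej + sum(da$p < alpha)
    tot <- tot + nrow(da)
  }
  list(rate = rej / tot, n_tests = tot)
}
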