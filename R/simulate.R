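# Generative model of an IgA-seq cohort.
#
# Each subject carries a presort community p (Dirichlet around a group base
# composition). Each taxon t has a latent coating probability theta[t, g]
# (the quantity the ICI estimates), realized per subject with Beta
# overdispersion. Magnetic sorting splits cells into an IgA+ and an IgA-
# pool with symmetric cross-contamination eps, and each of the three
# fractions is sequenced multinomially at a lognormal depth.

#' Simulation configuration for a sorted-fraction IgA-seq cohort
#'
#' Defaults emulate the cohort scale the pipeline is designed for: 575 taxa,
#' 16 control / 15 celiac subjects at age 2.5 and 13 / 9 at age 5, a mean
#' sequencing depth of 30,471 reads per sample, and group-level IgA+ flow
#' fractions of 6.02% (control) vs 12.8% (celiac) at age 5.
#'
#' @param n_taxa Number of taxa S.
#' @param group_sizes Named list: one element per age, each a named vector
#'   `c(control =, celiac =)` of subject counts.
#' @param base_log_sd Log-normal sigma of the base community abundances
#'   (right-skewed, as amplicon communities are).
#' @param subject_conc Dirichlet concentration scaling for per-subject
#'   presort compositions; lower values mean more inter-subject variation.
#' @param effect_taxa Integer indices of taxa whose presort abundance differs
#'   between groups; `effect_log2fc` gives the log2 fold-change (celiac over
#'   control) applied to the base abundance, recycled to length.
#' @param coating_shape1,coating_shape2 Beta shape parameters for per-taxon
#'   coating affinities (shared between groups before calibration).
#' @param flow_target Named numeric: target expected IgA+ (coated) fraction
#'   per group-age, names `"<group>_<age>"`. Coating probabilities are scaled
#'   so the expected flow-cytometry IgA+ fraction matches these.
#' @param coating_effect_taxa Integer indices of taxa whose coating affinity
#'   is shifted in the celiac group; `coating_log2or` gives the log2
#'   multiplier applied before flow calibration (recycled), so planted
#'   coating enrichment persists while the group flow fraction stays on
#'   target.
#' @param coating_theta_control,coating_theta_celiac Optional length-S
#'   vectors of explicit coating probabilities (overriding the affinity draw
#'   and flow calibration; used for planted-truth scenarios).
#' @param kappa Beta overdispersion of subject-level realized coating around
#'   theta (higher = less subject-to-subject variation).
#' @param impurity Symmetric sorting cross-contamination eps in [0, 0.5];
#'   0 is a perfect sort, 0.5 complete mixing.
#' @param depth_mean,depth_cv Mean and coefficient of variation of the
#'   per-sample sequencing depth (rounded log-normal).
#' @param seed Root RNG seed; named substreams are derived per stage.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 575,
                       group_sizes = list(
                         "2.5" = c(control = 16, celiac = 15),
                         "5" = c(control = 13, celiac = 9)),
                       base_log_sd = 2,
                       subject_conc = 50,
                       effect_taxa = integer(0),
                       effect_log2fc = numeric(0),
                       coating_shape1 = 0.6,
                       coating_shape2 = 8,
                       flow_target = c(control_2.5 = 0.055, celiac_2.5 = 0.065,
                                       control_5 = 0.0602, celiac_5 = 0.128),
                       coating_effect_taxa = integer(0),
                       coating_log2or = numeric(0),
                       coating_theta_control = NULL,
                       coating_theta_celiac = NULL,
                       kappa = 30,
                       impurity = 0.05,
                       depth_mean = 30471,
                       depth_cv = 0.3,
                       seed = 1) {
  if (n_taxa < 1) stop("n_taxa must be >= 1", call. = FALSE)
  if (impurity < 0 || impurity > 0.5)
    stop("impurity must lie in [0, 0.5]", call. = FALSE)
  if (depth_mean < 1) stop("depth_mean must be >= 1", call. = FALSE)
  if (base_log_sd < 0 || subject_conc <= 0 || kappa <= 0 ||
      coating_shape1 <= 0 || coating_shape2 <= 0)
    stop("dispersion/concentration parameters must be positive", call. = FALSE)
  for (th in list(coating_theta_control, coating_theta_celiac)) {
    if (!is.null(th) && (length(th) != n_taxa || any(th <= 0) || any(th >= 1)))
      stop("explicit coating probabilities must be length n_taxa in (0, 1)",
           call. = FALSE)
  }
  if (length(effect_taxa) > 0) {
    effect_log2fc <- rep_len(effect_log2fc, length(effect_taxa))
    if (any(effect_taxa < 1 | effect_taxa > n_taxa))
      stop("effect_taxa indices out of range", call. = FALSE)
  }
  if (length(coating_effect_taxa) > 0) {
    coating_log2or <- rep_len(coating_log2or, length(coating_effect_taxa))
    if (any(coating_effect_taxa < 1 | coating_effect_taxa > n_taxa))
      stop("coating_effect_taxa indices out of range", call. = FALSE)
  }
  structure(list(
    n_taxa = n_taxa, group_sizes = group_sizes, base_log_sd = base_log_sd,
    subject_conc = subject_conc, effect_taxa = effect_taxa,
    effect_log2fc = effect_log2fc, coating_shape1 = coating_shape1,
    coating_shape2 = coating_shape2, flow_target = flow_target,
    coating_effect_taxa = coating_effect_taxa,
    coating_log2or = coating_log2or,
    coating_theta_control = coating_theta_control,
    coating_theta_celiac = coating_theta_celiac,
    kappa = kappa, impurity = impurity, depth_mean = depth_mean,
    depth_cv = depth_cv, seed = seed), class = "sim_config")
}

#' Derive a deterministic per-stage seed from a root seed
#'
#' Named substreams keep each simulation stage reproducible independently of
#' the others. Result is always a valid 32-bit seed.
#'
#' @param seed Root integer seed.
#' @param stage Stage name.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647L)
}

#' Expected IgA+ / IgA- compositions after an impure sort
#'
#' Mechanistic model of magnetic sorting: a cell of taxon t is coated with
#' probability `theta[t]`; coated cells report to the IgA+ pool with
#' probability `1 - eps` (cross-contaminating the IgA- pool with probability
#' `eps`), and symmetrically for uncoated cells. With a perfect sort
#' (`eps = 0`) the IgA+ composition is proportional to `p * theta` and the
#' IgA- composition to `p * (1 - theta)`; at `eps = 0.5` both pools equal
#' the presort composition.
#'
#' @param p Presort composition (sums to 1).
#' @param theta Per-taxon coating probabilities in (0, 1).
#' @param eps Cross-contamination in [0, 0.5].
#' @return List with unit-sum vectors `pos` and `neg`.
#' @export
expected_sorted_compositions <- function(p, theta, eps) {
  if (length(p) != length(theta))
    stop("p and theta must have equal length", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("p must sum to 1 (within 1e-9); got ", format(sum(p)), call. = FALSE)
  if (any(theta <= 0) || any(theta >= 1))
    stop("theta must lie strictly in (0, 1)", call. = FALSE)
  if (eps < 0 || eps > 0.5) stop("eps must lie in [0, 0.5]", call. = FALSE)
  wpos <- p * ((1 - eps) * theta + eps * (1 - theta))
  wneg <- p * ((1 - eps) * (1 - theta) + eps * theta)
  list(pos = wpos / sum(wpos), neg = wneg / sum(wneg))
}

# Calibrate per-group coating probabilities so the expected coated fraction
# sum(base * theta) hits the flow target. Monotone in the scale factor, so a
# single uniroot call suffices; probabilities are capped below 0.95.
calibrate_theta <- function(affinity, base, target) {
  cap <- 0.95
  f <- function(s) sum(base * pmin(affinity * s, cap)) - target
  upper <- 1
  while (f(upper) < 0 && upper < 1e6) upper <- upper * 2
  s <- stats::uniroot(f, c(1e-9, upper), tol = 1e-12)$root
  pmin(pmax(affinity * s, 1e-4), cap)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate a full sorted-fraction IgA-seq cohort
#'
#' Draws group base compositions, per-taxon coating probabilities calibrated
#' to the configured flow-fraction targets, per-subject presort communities
#' and realized coating, then sequences presort / IgA+ / IgA- fractions
#' multinomially. Identical seeds give identical output.
#'
#' @param config A [sim_config()].
#' @return List with elements `counts` (a `count_table`, 3 samples per
#'   subject), `metadata` (a `sample_metadata`), and `truth`: per-age lists
#'   of base compositions, mean and realized coating probabilities,
#'   per-subject presort compositions, expected sorted compositions and flow
#'   fractions, plus the config.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  S <- config$n_taxa
  taxa <- sprintf("ASV%04d", seq_len(S))

  set.seed(stage_seed(config$seed, "base"))
  w <- exp(stats::rnorm(S, 0, config$base_log_sd))
  base <- list(control = w / sum(w))
  wc <- w
  if (length(config$effect_taxa) > 0)
    wc[config$effect_taxa] <- wc[config$effect_taxa] * 2^config$effect_log2fc
  base$celiac <- wc / sum(wc)

  set.seed(stage_seed(config$seed, "coating"))
  affinity <- stats::rbeta(S, config$coating_shape1, config$coating_shape2)
  theta <- list()
  for (age in names(config$group_sizes)) {
    th_age <- matrix(NA_real_, S, 2, dimnames = list(taxa, c("control", "celiac")))
    for (grp in c("control", "celiac")) {
      override <- config[[paste0("coating_theta_", grp)]]
      if (!is.null(override)) {
        th_age[, grp] <- override
      } else {
        key <- paste0(grp, "_", age)
        tgt <- config$flow_target[[key]]
        if (is.null(tgt) || is.na(tgt))
          stop("no flow_target entry for '", key, "'", call. = FALSE)
        aff <- affinity
        if (grp == "celiac" && length(config$coating_effect_taxa) > 0) {
          idx <- config$coating_effect_taxa
          aff[idx] <- aff[idx] * 2^config$coating_log2or
        }
        th_age[, grp] <- calibrate_theta(aff, base[[grp]], tgt)
      }
    }
    theta[[age]] <- th_age
  }

  set.seed(stage_seed(config$seed, "cohort"))
  sigma2 <- log(1 + config$depth_cv^2)
  meanlog <- log(config$depth_mean) - sigma2 / 2
  rows_meta <- list(); cols <- list(); truth_age <- list()
  for (age in names(config$group_sizes)) {
    p_mat <- NULL; theta_real <- NULL; flow <- c(); subj_grp <- c()
    for (grp in c("control", "celiac")) {
      n_sub <- config$group_sizes[[age]][[grp]]
      for (i in seq_len(n_sub)) {
        sid <- sprintf("%s%02d_a%s", substr(grp, 1, 3), i, age)
        p_s <- rdirichlet1(base[[grp]] * config$subject_conc)
        th <- pmin(pmax(theta[[age]][, grp], 1e-6), 1 - 1e-6)
        th_s <- stats::rbeta(S, th * config$kappa, (1 - th) * config$kappa)
        th_s <- pmin(pmax(th_s, 1e-9), 1 - 1e-9)
        q <- expected_sorted_compositions(p_s, th_s, config$impurity)
        depths <- pmax(1, round(stats::rlnorm(3, meanlog, sqrt(sigma2))))
        cnt_pre <- stats::rmultinom(1, depths[1], p_s)
        cnt_pos <- stats::rmultinom(1, depths[2], q$pos)
        cnt_neg <- stats::rmultinom(1, depths[3], q$neg)
        for (fr in c("presort", "igapos", "iganeg")) {
          rows_meta[[length(rows_meta) + 1]] <- data.frame(
            sample_id = paste0(sid, "_", fr), subject_id = sid, group = grp,
            age = as.numeric(age), fraction = fr, stringsAsFactors = FALSE)
        }
        cols[[length(cols) + 1]] <- cbind(cnt_pre, cnt_pos, cnt_neg)
        p_mat <- cbind(p_mat, p_s)
        theta_real <- cbind(theta_real, th_s)
        flow <- c(flow, stats::setNames(sum(p_s * th_s), sid))
        subj_grp <- c(subj_grp, stats::setNames(grp, sid))
      }
    }
    colnames(p_mat) <- names(flow); colnames(theta_real) <- names(flow)
    rownames(p_mat) <- taxa; rownames(theta_real) <- taxa
    truth_age[[age]] <- list(theta = theta[[age]], p = p_mat,
                             theta_realized = theta_real, flow_fraction = flow,
                             subject_group = subj_grp)
  }
  meta <- sample_metadata(do.call(rbind, rows_meta))
  m <- do.call(cbind, cols)
  tab <- count_table(m, taxon_ids = taxa, sample_ids = meta$sample_id)
  list(counts = tab, metadata = meta,
       truth = list(base = base, ages = truth_age, config = config))
}

#' Per-subject IgA+ flow-cytometry fractions from simulation truth
#'
#' The coated fraction of a subject's community is the dot product of its
#' presort composition with its realized per-taxon coating probabilities
#' (what a flow cytometer gating on IgA+ events measures). Optional Beta
#' measurement noise around the true value.
#'
#' @param truth The `truth` element of [simulate_cohort()] output.
#' @param noise_kappa If non-NULL, each fraction is re-drawn from a Beta
#'   distribution with this concentration around its true value.
#' @param seed Seed for measurement noise.
#' @return Data frame: subject_id, group, age, flow_fraction.
#' @export
simulate_flow_fractions <- function(truth, noise_kappa = NULL, seed = 1) {
  out <- list()
  for (age in names(truth$ages)) {
    ta <- truth$ages[[age]]
    out[[age]] <- data.frame(
      subject_id = names(ta$flow_fraction),
      group = unname(ta$subject_group),
      age = as.numeric(age),
      flow_fraction = unname(ta$flow_fraction),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(noise_kappa)) {
    set.seed(stage_seed(seed, "flow_noise"))
    f <- pmin(pmax(res$flow_fraction, 1e-9), 1 - 1e-9)
    res$flow_fraction <- stats::rbeta(length(f), f * noise_kappa,
                                      (1 - f) * noise_kappa)
  }
  res
}

#' Simulate a plasma analyte feature table with planted effects
#'
#' Log-normal feature intensities for two groups, with chosen features
#' shifted by a log2 fold-change in the celiac group. Mirrors the structure
#' of a targeted metabolomics / cytokine panel.
#'
#' @param n_features Number of features.
#' @param n_per_group Named vector `c(control =, celiac =)` of sample counts.
#' @param effect_features Integer indices of features with a group effect.
#' @param effect_log2fc Log2 fold-changes (celiac over control), recycled.
#' @param sdlog Log-scale noise standard deviation.
#' @param meanlog Log-scale baseline mean.
#' @param seed RNG seed.
#' @return List with `features` (a `feature_table`), `metadata`
#'   (a data frame with sample_id and group) and `truth` (per-feature true
#'   log2 fold-change).
#' @export
simulate_feature_table <- function(n_features, n_per_group = c(control = 9, celiac = 7),
                                   effect_features = integer(0),
                                   effect_log2fc = numeric(0),
                                   sdlog = 0.4, meanlog = 0, seed = 1) {
  if (n_features < 1) stop("n_features must be >= 1", call. = FALSE)
  effect_log2fc <- if (length(effect_features) > 0)
    rep_len(effect_log2fc, length(effect_features)) else numeric(0)
  set.seed(stage_seed(seed, "features"))
  true_l2fc <- numeric(n_features)
  true_l2fc[effect_features] <- effect_log2fc
  ids <- sprintf("feat%03d", seq_len(n_features))
  cols <- list(); grp <- character(0)
  for (g in c("control", "celiac")) {
    n <- n_per_group[[g]]
    shift <- if (g == "celiac") true_l2fc * log(2) else numeric(n_features)
    m <- matrix(stats::rlnorm(n_features * n, meanlog + shift, sdlog),
                nrow = n_features)
    cols[[g]] <- m
    grp <- c(grp, rep(g, n))
  }
  vals <- do.call(cbind, cols)
  snames <- sprintf("%s%02d", substr(grp, 1, 3), unlist(lapply(table(grp)[unique(grp)], seq_len)))
  ft <- feature_table(vals, feature_ids = ids, sample_ids = snames)
  list(features = ft,
       metadata = data.frame(sample_id = snames, group = grp,
                             stringsAsFactors = FALSE),
       truth = data.frame(feature_id = ids, log2fc = true_l2fc,
                          stringsAsFactors = FALSE))
}
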