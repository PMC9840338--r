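# Two-group screens: presort differential abundance, differential IgA
# targeting, the composite "comparable abundance but differentially
# targeted" call, the >1% mean-abundance t-test screen at an agglomerated
# rank, and the plasma-analyte volcano screen.

select_fraction <- function(counts, metadata, fraction, age) {
  metadata <- sample_metadata(as.data.frame(metadata))
  check_sample_join(colnames(counts), metadata$sample_id)
  sel <- metadata$fraction == fraction & metadata$age == age
  if (!any(sel))
    stop("no samples for fraction '", fraction, "' at age ", age, call. = FALSE)
  list(ids = metadata$sample_id[sel],
       group = metadata$group[sel])
}

#' Two-group differential abundance by permutation test
#'
#' For each taxon, per-sample relative abundances (with a pseudocount) are
#' compared between celiac and control by a permutation test on the absolute
#' difference of group means; p-values are BH-adjusted and significance is
#' the conjunction `q < q_max AND p < p_max`. Log2 fold-changes are computed
#' on the pseudocounted group mean relative abundances (celiac over
#' control), so they are always finite.
#'
#' @param counts A `count_table`.
#' @param metadata Matching `sample_metadata`.
#' @param fraction Which fraction to screen (`"presort"`, `"igapos"`,
#'   `"iganeg"`).
#' @param age Age (years) to select.
#' @param pseudocount Reads added per cell before normalization.
#' @param q_max,p_max Conjunctive significance thresholds.
#' @param transform Scale on which the permutation statistic (absolute
#'   difference of group means) is computed: `"log2"` (default; log2 of
#'   pseudocounted proportions, appropriate for heavy-tailed abundance
#'   data) or `"identity"` (raw proportions).
#' @param n_perm Sampled permutations when exhaustive enumeration exceeds
#'   `exhaustive_max` arrangements.
#' @param seed RNG seed for sampled mode.
#' @param exhaustive_max Cap on enumerated label arrangements.
#' @return Data frame of class `differential_result`: taxon/feature id,
#'   `log2fc`, `p`, `q`, `significant`, plus the test settings as
#'   attributes.
#' @export
differential_abundance <- function(counts, metadata, fraction = "presort", age,
                                   pseudocount = 1, q_max = 0.05, p_max = 0.01,
                                   transform = c("log2", "identity"),
                                   n_perm = 4999, seed = 1,
                                   exhaustive_max = 20000) {
  transform <- match.arg(transform)
  sel <- select_fraction(counts, metadata, fraction, age)
  if (sum(sel$group == "control") < 2 || sum(sel$group == "celiac") < 2)
    stop("need at least 2 samples per group at fraction '", fraction,
         "', age ", age, call. = FALSE)
  rel <- relative_abundance(counts[, sel$ids, drop = FALSE], pseudocount)
  V <- t(rel)                                   # samples x taxa
  if (transform == "log2") {
    if (pseudocount <= 0 && any(V == 0))
      stop("log2 transform needs a positive pseudocount", call. = FALSE)
    V <- log2(V)
  }
  idx_cel <- which(sel$group == "celiac")
  res <- perm_test_matrix(V, idx_cel, n1 = length(idx_cel), n_perm = n_perm,
                          seed = seed, exhaustive_max = exhaustive_max)
  # fold-change always on the arithmetic pseudocounted group means
  mean_cel <- rowMeans(rel[, idx_cel, drop = FALSE])
  mean_ctl <- rowMeans(rel[, -idx_cel, drop = FALSE])
  q <- bh_fdr(res$p)
  out <- data.frame(feature_id = rownames(counts),
                    log2fc = log2(mean_cel / mean_ctl),
                    p = res$p, q = q,
                    significant = q < q_max & res$p < p_max,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "test") <- list(engine = "permutation", fraction = fraction,
                            age = age, pseudocount = pseudocount,
                            transform = transform,
                            q_max = q_max, p_max = p_max,
                            n_perm = res$n_perm, exhaustive = res$exhaustive,
                            seed = seed)
  class(out) <- c("differential_result", class(out))
  out
}

#' Composite call: comparable presort abundance, differential IgA targeting
#'
#' A taxon is "differentially targeted" when its presort abundance does not
#' differ between groups (BH-adjusted presort q at or above the
#' comparability floor) while its IgA coating does (significant on the
#' chosen coating signal). The coating signal is the IgA+ fraction by
#' default; the IgA- fraction or per-subject ICI values are selectable.
#'
#' @inheritParams differential_abundance
#' @param coating_on Coating signal: `"ici"` (default; per-subject ICI
#'   values, pairing the sorted fractions within subject, which cancels
#'   between-subject compositional variance), `"igapos"`, or `"iganeg"`.
#' @param comparability_q Presort taxa with `q >= comparability_q` count as
#'   comparable.
#' @return Data frame of class `targeting_call`: per-taxon flags
#'   `presort_comparable`, `coating_differential`,
#'   `differentially_targeted`, with the presort and coating screens as
#'   attributes.
#' @export
differential_targeting <- function(counts, metadata, age,
                                   coating_on = c("ici", "igapos", "iganeg"),
                                   comparability_q = 0.05,
                                   pseudocount = 1, q_max = 0.05, p_max = 0.01,
                                   transform = c("log2", "identity"),
                                   n_perm = 4999, seed = 1,
                                   exhaustive_max = 20000) {
  coating_on <- match.arg(coating_on)
  transform <- match.arg(transform)
  pre <- differential_abundance(counts, metadata, "presort", age,
                                pseudocount, q_max, p_max, transform,
                                n_perm, stage_seed(seed, "presort"),
                                exhaustive_max)
  if (coating_on %in% c("igapos", "iganeg")) {
    coat <- differential_abundance(counts, metadata, coating_on, age,
                                   pseudocount, q_max, p_max, transform,
                                   n_perm, stage_seed(seed, "coating"),
                                   exhaustive_max)
  } else {
    coat <- ici_differential(counts, metadata, age, pseudocount, q_max, p_max,
                             n_perm, stage_seed(seed, "coating"),
                             exhaustive_max)
  }
  out <- data.frame(taxon_id = pre$feature_id,
                    presort_comparable = pre$q >= comparability_q,
                    coating_differential = coat$significant,
                    stringsAsFactors = FALSE)
  out$differentially_targeted <- out$presort_comparable & out$coating_differential
  attr(out, "presort_screen") <- pre
  attr(out, "coating_screen") <- coat
  attr(out, "coating_on") <- coating_on
  attr(out, "comparability_q") <- comparability_q
  class(out) <- c("targeting_call", class(out))
  out
}

# Per-subject ICI values per taxon, screened between groups by permutation
# test on log2(ICI) (log scale symmetrizes the ratio).
ici_differential <- function(counts, metadata, age, pseudocount = 1,
                             q_max = 0.05, p_max = 0.01, n_perm = 4999,
                             seed = 1, exhaustive_max = 20000) {
  metadata <- sample_metadata(as.data.frame(metadata))
  sel <- metadata$age == age & metadata$fraction != "presort"
  md <- metadata[sel, , drop = FALSE]
  subjects <- unique(md$subject_id)
  rel <- relative_abundance(counts[, md$sample_id, drop = FALSE], pseudocount)
  ici_sub <- vapply(subjects, function(s) {
    pos <- md$sample_id[md$subject_id == s & md$fraction == "igapos"]
    neg <- md$sample_id[md$subject_id == s & md$fraction == "iganeg"]
    log2(ici_per_taxon(rel[, pos], rel[, neg]))
  }, numeric(nrow(counts)))
  grp <- md$group[match(subjects, md$subject_id)]
  V <- t(ici_sub)
  idx_cel <- which(grp == "celiac")
  res <- perm_test_matrix(V, idx_cel, n1 = length(idx_cel), n_perm = n_perm,
                          seed = seed, exhaustive_max = exhaustive_max)
  q <- bh_fdr(res$p)
  data.frame(feature_id = rownames(counts),
             log2fc = colMeans(V[idx_cel, , drop = FALSE]) -
               colMeans(V[-idx_cel, , drop = FALSE]),
             p = res$p, q = q, significant = q < q_max & res$p < p_max,
             stringsAsFactors = FALSE)
}

#' Volcano screen for plasma analytes
#'
#' Per-feature two-tailed Welch t-test between groups, with volcano
#' significance gated on both a fold-change threshold (`|log2FC| >
#' fc_threshold`) and a p-value threshold (`-log10(p) > logp_threshold`).
#' BH-adjusted q-values are reported alongside for FDR-based tallies.
#' Features constant in both groups get `p = 1` and a warning flag.
#'
#' @param features A `feature_table` (features x samples).
#' @param group Character vector of group labels (`control`/`celiac`)
#'   aligned with the columns of `features`, or a metadata data frame with
#'   `sample_id` and `group` columns.
#' @param fc_threshold Gate on `|log2FC|` (strict; default 1.2).
#' @param logp_threshold Gate on `-log10(p)` (strict; default 0.1).
#' @return Data frame of class `differential_result` with columns
#'   `feature_id`, `log2fc`, `p`, `q`, `volcano_significant`,
#'   `volcano_class` (`"up"`, `"down"`, `"ns"`), `constant_flag`.
#' @export
volcano_screen <- function(features, group, fc_threshold = 1.2,
                           logp_threshold = 0.1) {
  m <- unclass(as.matrix(features))
  if (is.data.frame(group)) {
    group <- group$group[match(colnames(m), group$sample_id)]
  }
  if (length(group) != ncol(m))
    stop("group labels must align with feature table columns", call. = FALSE)
  i1 <- group == "celiac"; i2 <- group == "control"
  if (sum(i1) < 2 || sum(i2) < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  p <- numeric(nrow(m)); constant <- logical(nrow(m))
  for (f in seq_len(nrow(m))) {
    x <- m[f, i1]; y <- m[f, i2]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      p[f] <- 1; constant[f] <- TRUE
    } else {
      p[f] <- stats::t.test(x, y, var.equal = FALSE)$p.value
    }
  }
  if (any(constant))
    warning(sum(constant), " feature(s) constant in both groups; p set to 1")
  l2fc <- log2(rowMeans(m[, i1, drop = FALSE]) / rowMeans(m[, i2, drop = FALSE]))
  sig <- abs(l2fc) > fc_threshold & -log10(p) > logp_threshold
  out <- data.frame(feature_id = rownames(m), log2fc = l2fc, p = p,
                    q = bh_fdr(p),
                    volcano_significant = sig,
                    volcano_class = ifelse(!sig, "ns",
                                           ifelse(l2fc > 0, "up", "down")),
                    constant_flag = constant,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "test") <- list(engine = "welch_t", fc_threshold = fc_threshold,
                            logp_threshold = logp_threshold)
  class(out) <- c("differential_result", class(out))
  out
}

#' Mean relative-abundance screen at an agglomerated rank
#'
#' Restricts to taxa whose overall mean relative abundance exceeds
#' `min_mean_abundance` (strict >, default 1%), then compares per-sample
#' relative abundances between groups with two-tailed Welch t-tests and BH
#' correction.
#'
#' @inheritParams differential_abundance
#' @param taxonomy A `taxonomy_table` for agglomeration.
#' @param rank Taxonomic rank (e.g. `"phylum"`, `"genus"`).
#' @param min_mean_abundance Inclusion threshold on overall mean proportion.
#' @return `differential_result` data frame over the retained rank labels
#'   (zero rows, with a message, when nothing passes the filter).
#' @export
group_mean_relabund_screen <- function(counts, metadata, taxonomy, rank,
                                       fraction = "presort", age,
                                       min_mean_abundance = 0.01,
                                       q_max = 0.05) {
  agg <- agglomerate(counts, taxonomy, rank)
  sel <- select_fraction(agg, metadata, fraction, age)
  rel <- relative_abundance(agg[, sel$ids, drop = FALSE], pseudocount = 0)
  keep <- rowMeans(rel) > min_mean_abundance
  if (!any(keep)) {
    message("no taxa exceed mean relative abundance ", min_mean_abundance,
            " at rank ", rank)
    out <- data.frame(feature_id = character(0), log2fc = numeric(0),
                      p = numeric(0), q = numeric(0), significant = logical(0))
    class(out) <- c("differential_result", class(out))
    return(out)
  }
  rel <- rel[keep, , drop = FALSE]
  i1 <- sel$group == "celiac"; i2 <- sel$group == "control"
  p <- vapply(seq_len(nrow(rel)), function(t) {
    x <- rel[t, i1]; y <- rel[t, i2]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(1)
    stats::t.test(x, y, var.equal = FALSE)$p.value
  }, numeric(1))
  q <- bh_fdr(p)
  out <- data.frame(feature_id = rownames(rel),
                    log2fc = log2(rowMeans(rel[, i1, drop = FALSE]) /
                                    rowMeans(rel[, i2, drop = FALSE])),
                    p = p, q = q, significant = q < q_max,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "test") <- list(engine = "welch_t", rank = rank,
                            min_mean_abundance = min_mean_abundance,
                            fraction = fraction, age = age)
  class(out) <- c("differential_result", class(out))
  out
}
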