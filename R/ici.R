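# The IgA coating index (ICI): for each taxon, the ratio of its relative
# abundance in the IgA+ fraction to its relative abundance in the IgA-
# fraction. ICI >> 1 marks preferential targeting by mucosal IgA.

#' Column-wise relative abundance with an optional pseudocount
#'
#' @param table A `count_table` (or bare non-negative matrix).
#' @param pseudocount Reads added to every cell before normalization
#'   (default 0). A pseudocount of 1 guarantees strictly positive
#'   proportions, which the ICI ratio requires.
#' @return Matrix of proportions (columns sum to 1) with attribute
#'   `pseudocount`.
#' @export
relative_abundance <- function(table, pseudocount = 0) {
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  m <- unclass(as.matrix(table)) + pseudocount
  tot <- colSums(m)
  if (any(tot <= 0))
    stop("degenerate sample(s) with zero total counts and pseudocount 0: ",
         paste(colnames(m)[tot <= 0], collapse = ", "), call. = FALSE)
  out <- sweep(m, 2, tot, "/")
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Per-taxon IgA coating index from matched composition vectors
#'
#' `ICI_t = rel_pos_t / rel_neg_t`, the ratio of a taxon's relative abundance
#' in the IgA+ sample to its relative abundance in the IgA- sample.
#'
#' @param rel_pos,rel_neg Matched vectors of strictly positive proportions
#'   (use a pseudocount upstream to avoid zeros).
#' @return Numeric vector of finite positive ratios.
#' @export
ici_per_taxon <- function(rel_pos, rel_neg) {
  if (length(rel_pos) != length(rel_neg))
    stop("rel_pos and rel_neg must be matched vectors", call. = FALSE)
  if (any(rel_neg == 0))
    stop("zero IgA- relative abundance: ICI is undefined; ",
         "set a positive pseudocount when computing relative abundances",
         call. = FALSE)
  rel_pos / rel_neg
}

#' Group-level ICI per taxon
#'
#' Two estimators are offered, since the published quantity is one ICI per
#' taxon per group without a stated aggregation:
#' `"pooled_mean"` (default) divides the group's mean IgA+ relative abundance
#' by its mean IgA- relative abundance; `"subject_median"` computes a
#' per-subject ICI first and takes the median across subjects.
#'
#' @param counts A `count_table` containing igapos/iganeg samples.
#' @param metadata Matching `sample_metadata`.
#' @param group `"control"` or `"celiac"`.
#' @param age Age (years) to select.
#' @param method Aggregation estimator.
#' @param pseudocount Reads added per cell before normalization (default 1).
#' @return Named numeric vector of per-taxon group ICI values.
#' @export
group_ici <- function(counts, metadata, group, age,
                      method = c("pooled_mean", "subject_median"),
                      pseudocount = 1) {
  method <- match.arg(method)
  metadata <- sample_metadata(as.data.frame(metadata))
  check_sample_join(colnames(counts), metadata$sample_id)
  sel <- metadata$group == group & metadata$age == age
  pos_ids <- metadata$sample_id[sel & metadata$fraction == "igapos"]
  neg_ids <- metadata$sample_id[sel & metadata$fraction == "iganeg"]
  if (length(pos_ids) == 0 || length(neg_ids) == 0)
    stop("no sorted igapos/iganeg pairs for group '", group, "' at age ", age,
         call. = FALSE)
  rel <- relative_abundance(counts[, c(pos_ids, neg_ids), drop = FALSE],
                            pseudocount = pseudocount)
  if (method == "pooled_mean") {
    ici <- rowMeans(rel[, pos_ids, drop = FALSE]) /
      rowMeans(rel[, neg_ids, drop = FALSE])
  } else {
    subj_pos <- metadata$subject_id[match(pos_ids, metadata$sample_id)]
    subj_neg <- metadata$subject_id[match(neg_ids, metadata$sample_id)]
    common <- intersect(subj_pos, subj_neg)
    per_sub <- vapply(common, function(s) {
      ici_per_taxon(rel[, pos_ids[subj_pos == s]], rel[, neg_ids[subj_neg == s]])
    }, numeric(nrow(rel)))
    ici <- apply(per_sub, 1, stats::median)
  }
  stats::setNames(as.numeric(ici), rownames(counts))
}

#' Retention rule for the ICI heatmap
#'
#' Taxa with ICI below 1 in both groups are discarded; a taxon is kept when
#' its ICI is at least 1 in both groups, or when the two groups disagree
#' about the direction of coating (one ICI below 1 and the other above 1 —
#' the "discordant" exception). A boundary value of exactly 1 is not "lower
#' than 1" and is therefore retained.
#'
#' @param ici_control,ici_celiac Finite positive per-taxon group ICI values.
#' @return Data frame with logical columns `retained` and `discordant`.
#' @export
retention_filter <- function(ici_control, ici_celiac) {
  if (length(ici_control) != length(ici_celiac))
    stop("group ICI vectors must be matched", call. = FALSE)
  if (any(!is.finite(ici_control)) || any(!is.finite(ici_celiac)) ||
      any(ici_control <= 0) || any(ici_celiac <= 0))
    stop("ICI values must be finite and positive", call. = FALSE)
  discordant <- (ici_control < 1 & ici_celiac > 1) |
    (ici_control > 1 & ici_celiac < 1)
  retained <- (pmin(ici_control, ici_celiac) >= 1) | discordant
  data.frame(retained = retained, discordant = discordant)
}

#' Row-wise z-score normalization for heatmap display
#'
#' Each row is centered on its mean and scaled by its sample standard
#' deviation (n - 1 denominator). Constant rows map to all zeros rather than
#' NaN.
#'
#' @param m Numeric matrix with at least 2 columns.
#' @return Matrix of the same shape.
#' @export
normalize_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("row normalization needs >= 2 columns", call. = FALSE)
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  out <- (m - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}

#' High-coater calls: taxa with group ICI above a threshold
#'
#' @param ici Named numeric vector of group ICI values (one group).
#' @param threshold Strict threshold (default 10; `ICI > 10` is flagged,
#'   `ICI == 10` is not).
#' @return Character vector of taxon ids.
#' @export
high_coaters <- function(ici, threshold = 10) {
  as.character(names(ici)[is.finite(ici) & ici > threshold])
}

#' Full ICI table for one age: group ICIs, flags, and heatmap matrix
#'
#' Computes per-group ICI values, applies the retention/discordance rule,
#' flags high-coaters, and builds the row-normalized heatmap matrix over the
#' retained taxa. Heatmap columns are the two group ICIs, optionally
#' augmented with group mean IgA+ relative abundances.
#'
#' @inheritParams group_ici
#' @param high_threshold High-coater threshold on group ICI (strict).
#' @param include_abundance Add group mean IgA+ relative-abundance columns
#'   to the heatmap matrix.
#' @return List of class `ici_table`: `table` (per-taxon data frame with
#'   ici_control, ici_celiac, retained, discordant, high_coater_control,
#'   high_coater_celiac), `heatmap` (z-scored matrix over retained taxa),
#'   and the parameters used.
#' @export
ici_table <- function(counts, metadata, age,
                      method = c("pooled_mean", "subject_median"),
                      pseudocount = 1, high_threshold = 10,
                      include_abundance = FALSE) {
  method <- match.arg(method)
  ici_c <- group_ici(counts, metadata, "control", age, method, pseudocount)
  ici_d <- group_ici(counts, metadata, "celiac", age, method, pseudocount)
  flags <- retention_filter(ici_c, ici_d)
  tab <- data.frame(taxon_id = rownames(counts),
                    ici_control = unname(ici_c), ici_celiac = unname(ici_d),
                    retained = flags$retained, discordant = flags$discordant,
                    high_coater_control = unname(ici_c > high_threshold),
                    high_coater_celiac = unname(ici_d > high_threshold),
                    stringsAsFactors = FALSE)
  hm_in <- cbind(ici_control = ici_c, ici_celiac = ici_d)[flags$retained, ,
                                                          drop = FALSE]
  if (include_abundance) {
    metadata <- sample_metadata(as.data.frame(metadata))
    rel <- relative_abundance(counts, pseudocount = pseudocount)
    for (grp in c("control", "celiac")) {
      ids <- metadata$sample_id[metadata$group == grp & metadata$age == age &
                                  metadata$fraction == "igapos"]
      hm_in <- cbind(hm_in, rowMeans(rel[flags$retained, ids, drop = FALSE]))
      colnames(hm_in)[ncol(hm_in)] <- paste0("relabund_", grp)
    }
  }
  heatmap <- if (nrow(hm_in) > 0) normalize_rows(hm_in) else hm_in
  structure(list(table = tab, heatmap = heatmap, age = age, method = method,
                 pseudocount = pseudocount, high_threshold = high_threshold),
            class = "ici_table")
}

#' @export
print.ici_table <- function(x, ...) {
  cat(sprintf(
    "ici_table (age %s, %s, pseudocount %g): %d taxa, %d retained (%d discordant), high-coaters (>%g): %d control / %d celiac\n",
    format(x$age), x$method, x$pseudocount, nrow(x$table), sum(x$table$retained),
    sum(x$table$discordant), x$high_threshold,
    sum(x$table$high_coater_control), sum(x$table$high_coater_celiac)))
  invisible(x)
}
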