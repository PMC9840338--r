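# End-to-end orchestration: run every analysis stage on a cohort and write
# TSV reports with provenance headers. The numbered scripts under analysis/
# are thin drivers over these functions.

provenance_header <- function(cfg) {
  vapply(names(cfg), function(k) paste0(k, "=", format(cfg[[k]], digits = 15)),
         character(1))
}

write_tsv_report <- function(df, path, header) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_report <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Run the full IgA-seq analysis on a cohort and write a report bundle
#'
#' For every age present in the metadata: the ICI table with retention and
#' high-coater flags plus the row-normalized heatmap matrix; permutation
#' differential-abundance screens on each fraction; the composite
#' differential-targeting call; observed richness; Bray-Curtis PERMANOVA of
#' group separation per fraction; and PCA coordinates. Every report carries
#' a `#`-prefixed provenance header echoing version, seed and thresholds.
#' Reruns with identical inputs and seed are byte-identical.
#'
#' @param counts A `count_table`.
#' @param metadata Matching `sample_metadata`.
#' @param out_dir Output directory (created if missing).
#' @param pseudocount Pseudocount for relative abundances in ICI and
#'   screens.
#' @param q_max,p_max Conjunctive significance thresholds for the
#'   permutation screens.
#' @param comparability_q Presort comparability floor for targeting calls.
#' @param high_threshold High-coater ICI threshold.
#' @param coating_on Coating signal for the targeting call.
#' @param n_perm Sampled permutation count.
#' @param n_perm_permanova Label permutations for PERMANOVA.
#' @param seed Root seed (per-stage substreams are derived from it).
#' @return Invisibly, a named list of written file paths.
#' @export
run_analysis <- function(counts, metadata, out_dir,
                         pseudocount = 1, q_max = 0.05, p_max = 0.01,
                         comparability_q = 0.05, high_threshold = 10,
                         coating_on = "ici",
                         n_perm = 4999, n_perm_permanova = 999, seed = 1) {
  metadata <- sample_metadata(as.data.frame(metadata))
  check_sample_join(colnames(counts), metadata$sample_id)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(list(
    igaseq_version = as.character(utils::packageVersion("igaseq")),
    seed = seed, pseudocount = pseudocount, q_max = q_max, p_max = p_max,
    comparability_q = comparability_q, ici_high_threshold = high_threshold,
    coating_on = coating_on, test_engine = "permutation_abs_mean_diff",
    n_perm = n_perm, n_perm_permanova = n_perm_permanova))
  paths <- list()
  ages <- sort(unique(metadata$age))
  for (age in ages) {
    tag <- gsub(".", "_", format(age), fixed = TRUE)
    it <- ici_table(counts, metadata, age, pseudocount = pseudocount,
                    high_threshold = high_threshold)
    paths[[paste0("ici_", tag)]] <- write_tsv_report(
      it$table, file.path(out_dir, paste0("ici_age", tag, ".tsv")), hdr)
    hm <- data.frame(taxon_id = rownames(it$heatmap),
                     as.data.frame(unclass(it$heatmap)),
                     stringsAsFactors = FALSE)
    paths[[paste0("heatmap_", tag)]] <- write_tsv_report(
      hm, file.path(out_dir, paste0("heatmap_age", tag, ".tsv")), hdr)
    for (fr in c("presort", "igapos", "iganeg")) {
      da <- differential_abundance(counts, metadata, fr, age,
                                   pseudocount = pseudocount, q_max = q_max,
                                   p_max = p_max, n_perm = n_perm,
                                   seed = stage_seed(seed, paste0(fr, age)))
      paths[[paste0("diff_", fr, "_", tag)]] <- write_tsv_report(
        da, file.path(out_dir, paste0("diff_", fr, "_age", tag, ".tsv")), hdr)
    }
    tg <- differential_targeting(counts, metadata, age,
                                 coating_on = coating_on,
                                 comparability_q = comparability_q,
                                 pseudocount = pseudocount, q_max = q_max,
                                 p_max = p_max, n_perm = n_perm,
                                 seed = stage_seed(seed, paste0("target", age)))
    paths[[paste0("targeting_", tag)]] <- write_tsv_report(
      tg, file.path(out_dir, paste0("targeting_age", tag, ".tsv")), hdr)
    # community statistics per fraction
    perm_rows <- list()
    for (fr in c("presort", "igapos", "iganeg")) {
      ids <- metadata$sample_id[metadata$fraction == fr & metadata$age == age]
      grp <- metadata$group[match(ids, metadata$sample_id)]
      if (length(ids) < 4 || length(unique(grp)) < 2) next
      d <- bray_curtis_matrix(counts[, ids, drop = FALSE])
      pr <- permanova(d, grp, n_perm = n_perm_permanova,
                      seed = stage_seed(seed, paste0("permanova", fr, age)))
      perm_rows[[fr]] <- data.frame(age = age, fraction = fr,
                                    pseudo_F = pr$pseudo_F, R2 = pr$R2,
                                    p = pr$p, n_perm = pr$n_perm,
                                    exhaustive = pr$exhaustive)
    }
    paths[[paste0("permanova_", tag)]] <- write_tsv_report(
      do.call(rbind, perm_rows),
      file.path(out_dir, paste0("permanova_age", tag, ".tsv")), hdr)
    ids_pre <- metadata$sample_id[metadata$fraction == "presort" &
                                    metadata$age == age]
    pc <- pca_ordination(counts[, ids_pre, drop = FALSE], n_components = 2)
    pcdf <- data.frame(sample_id = rownames(pc$scores),
                       PC1 = pc$scores[, 1], PC2 = pc$scores[, 2],
                       stringsAsFactors = FALSE)
    paths[[paste0("pca_", tag)]] <- write_tsv_report(
      pcdf, file.path(out_dir, paste0("pca_presort_age", tag, ".tsv")),
      c(hdr, paste0("explained=", paste(format(pc$explained, digits = 6),
                                        collapse = ","))))
  }
  rich <- observed_richness(counts)
  richdf <- data.frame(sample_id = names(rich), observed_asvs = unname(rich),
                       stringsAsFactors = FALSE)
  paths[["alpha"]] <- write_tsv_report(richdf, file.path(out_dir, "alpha.tsv"),
                                       hdr)
  invisible(paths)
}

#' Summarize a report bundle into human-readable tallies
#'
#' Reads the TSV reports written by [run_analysis()] and tallies significant
#' taxa per age and fraction, differential-targeting calls, and high-coater
#' counts per group, as markdown-ish text.
#'
#' @param out_dir Directory holding the report bundle.
#' @return Character vector of summary lines (also printed).
#' @export
report_summary <- function(out_dir) {
  files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(files) == 0)
    stop("no report files found in '", out_dir, "'; expected ici_age*.tsv, ",
         "diff_*_age*.tsv, targeting_age*.tsv, permanova_age*.tsv, alpha.tsv",
         call. = FALSE)
  lines <- c("# IgA-seq analysis summary", "")
  for (f in sort(files[grepl("diff_", basename(files))])) {
    df <- read_tsv_report(f)
    lines <- c(lines, sprintf("- %s: %d of %d taxa significant",
                              sub("\\.tsv$", "", basename(f)),
                              sum(df$significant), nrow(df)))
  }
  for (f in sort(files[grepl("targeting_", basename(files))])) {
    df <- read_tsv_report(f)
    lines <- c(lines, sprintf("- %s: %d differentially targeted taxa",
                              sub("\\.tsv$", "", basename(f)),
                              sum(df$differentially_targeted)))
  }
  for (f in sort(files[grepl("^ici_", basename(files))])) {
    df <- read_tsv_report(f)
    lines <- c(lines, sprintf(
      "- %s: %d retained taxa, high-coaters %d control / %d celiac",
      sub("\\.tsv$", "", basename(f)), sum(df$retained),
      sum(df$high_coater_control), sum(df$high_coater_celiac)))
  }
  writeLines(lines)
  invisible(lines)
}
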