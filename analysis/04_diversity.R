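#!/usr/bin/env Rscript
# Stage 4: community statistics — observed richness with one-way ANOVA per
# age, Bray-Curtis PERMANOVA of the group effect per fraction, and PCA
# ordination of the presort samples.
#
# Reads:  results/sim/{counts.tsv, metadata.tsv}
# Writes: results/diversity/{alpha.tsv, permanova.tsv, pca_age*.tsv}

suppressPackageStartupMessages(library(igaseq))
seed <- 1
inp <- read_count_table("results/sim/counts.tsv", "results/sim/metadata.tsv")
md <- inp$metadata
out <- "results/diversity"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

rich <- observed_richness(inp$counts)
utils::write.table(data.frame(sample_id = names(rich),
                              observed_asvs = unname(rich)),
                   file.path(out, "alpha.tsv"), sep = "\t", quote = FALSE,
                   row.names = FALSE)
for (age in sort(unique(md$age))) {
  ids <- md$sample_id[md$fraction == "presort" & md$age == age]
  a <- anova_oneway(rich[ids], md$group[match(ids, md$sample_id)])
  message(sprintf("age %s alpha diversity (observed ASVs) group ANOVA: F=%.2f p=%.3f",
                  format(age), a$F, a$p))
}

rows <- list()
for (age in sort(unique(md$age))) {
  for (fr in c("presort", "igapos", "iganeg")) {
    ids <- md$sample_id[md$fraction == fr & md$age == age]
    grp <- md$group[match(ids, md$sample_id)]
    d <- bray_curtis_matrix(inp$counts[, ids, drop = FALSE])
    pr <- permanova(d, grp, n_perm = 999,
                    seed = stage_seed(seed, paste0("pmv", fr, age)))
    rows[[paste(age, fr)]] <- data.frame(age = age, fraction = fr,
                                         pseudo_F = pr$pseudo_F, R2 = pr$R2,
                                         p = pr$p, n_perm = pr$n_perm)
    message(sprintf("age %s %-7s PERMANOVA (group): F=%.2f R2=%.3f p=%.3f",
                    format(age), fr, pr$pseudo_F, pr$R2, pr$p))
  }
}
utils::write.table(do.call(rbind, rows), file.path(out, "permanova.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

for (age in sort(unique(md$age))) {
  ids <- md$sample_id[md$fraction == "presort" & md$age == age]
  pc <- pca_ordination(inp$counts[, ids, drop = FALSE], n_components = 2)
  tag <- gsub(".", "_", format(age), fixed = TRUE)
  utils::write.table(
    data.frame(sample_id = rownames(pc$scores), PC1 = pc$scores[, 1],
               PC2 = pc$scores[, 2]),
    file.path(out, paste0("pca_age", tag, ".tsv")), sep = "\t",
    quote = FALSE, row.names = FALSE)
  message(sprintf("age %s presort PCA: PC1 %.1f%%, PC2 %.1f%% of variance",
                  format(age), 100 * pc$explained[1], 100 * pc$explained[2]))
}
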