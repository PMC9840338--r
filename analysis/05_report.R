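#!/usr/bin/env Rscript
# Stage 5: human-readable summary of the full report bundle, plus a check
# of recovery against the simulation ground truth.
#
# Reads:  results/{sim, ici, screens}
# Writes: results/summary.md

suppressPackageStartupMessages(library(igaseq))

lines <- c("# IgA-seq simulated cohort: analysis summary", "")
for (f in sort(list.files("results/screens", pattern = "^diff_.*\\.tsv$",
                          full.names = TRUE))) {
  df <- utils::read.delim(f, comment.char = "#")
  lines <- c(lines, sprintf("- %s: %d of %d taxa significant",
                            sub("\\.tsv$", "", basename(f)),
                            sum(df$significant), nrow(df)))
}
for (f in sort(list.files("results/screens", pattern = "^targeting_.*\\.tsv$",
                          full.names = TRUE))) {
  df <- utils::read.delim(f, comment.char = "#")
  lines <- c(lines, sprintf("- %s: %d differentially targeted taxa",
                            sub("\\.tsv$", "", basename(f)),
                            sum(df$differentially_targeted)))
}
for (f in sort(list.files("results/ici", pattern = "^ici_.*\\.tsv$",
                          full.names = TRUE))) {
  df <- utils::read.delim(f, comment.char = "#")
  lines <- c(lines, sprintf(
    "- %s: %d retained taxa, high-coaters (ICI>10): %d control / %d celiac",
    sub("\\.tsv$", "", basename(f)), sum(df$retained),
    sum(df$high_coater_control), sum(df$high_coater_celiac)))
}

# ground-truth checks against the planted effects and coating truth
inp <- read_count_table("results/sim/counts.tsv", "results/sim/metadata.tsv")
fx <- utils::read.delim("results/sim/planted_effects.tsv")
for (age in sort(unique(inp$metadata$age))) {
  tag <- gsub(".", "_", format(age), fixed = TRUE)
  th <- utils::read.delim(file.path("results/sim",
                                    paste0("theta_age", tag, ".tsv")))
  gi <- group_ici(inp$counts, inp$metadata, "celiac", age)
  rho <- cor(th$theta_celiac, gi[th$taxon_id], method = "spearman")
  lines <- c(lines, sprintf(
    "- age %s: Spearman(true coating probability, estimated celiac ICI) = %.3f (all %d taxa, incl. those below the detection limit)",
    format(age), rho, nrow(th)))
  pre <- utils::read.delim(file.path("results/screens",
                                     paste0("diff_presort_age", tag, ".tsv")))
  tgt <- utils::read.delim(file.path("results/screens",
                                     paste0("targeting_age", tag, ".tsv")))
  planted_pre <- fx$taxon_id[fx$effect == "presort_abundance"]
  planted_coat <- fx$taxon_id[fx$effect == "iga_coating"]
  lines <- c(lines, sprintf(
    "- age %s: %d/%d planted presort effects significant; %d/%d planted coating effects called differentially targeted",
    format(age),
    sum(pre$significant[pre$feature_id %in% planted_pre]), length(planted_pre),
    sum(tgt$differentially_targeted[tgt$taxon_id %in% planted_coat]),
    length(planted_coat)))
}

writeLines(lines)
writeLines(lines, "results/summary.md")
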