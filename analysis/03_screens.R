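#!/usr/bin/env Rscript
# Stage 3: two-group screens — presort and sorted-fraction differential
# abundance, the composite "comparable abundance but differentially
# IgA-targeted" call, and a volcano screen on a simulated plasma panel with
# a planted 1.92-fold analyte.
#
# Reads:  results/sim/{counts.tsv, metadata.tsv}
# Writes: results/screens/{diff_*_age*.tsv, targeting_age*.tsv, volcano.tsv}

suppressPackageStartupMessages(library(igaseq))
seed <- 1
inp <- read_count_table("results/sim/counts.tsv", "results/sim/metadata.tsv")
out <- "results/screens"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (age in sort(unique(inp$metadata$age))) {
  tag <- gsub(".", "_", format(age), fixed = TRUE)
  for (fr in c("presort", "igapos", "iganeg")) {
    da <- differential_abundance(inp$counts, inp$metadata, fr, age,
                                 seed = stage_seed(seed, paste0(fr, age)))
    utils::write.table(da, file.path(out, sprintf("diff_%s_age%s.tsv", fr, tag)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("age %s %-7s: %d/%d taxa significant (FDR<0.05 & p<0.01)",
                    format(age), fr, sum(da$significant), nrow(da)))
  }
  tg <- differential_targeting(inp$counts, inp$metadata, age,
                               seed = stage_seed(seed, paste0("tgt", age)))
  utils::write.table(tg, file.path(out, sprintf("targeting_age%s.tsv", tag)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("age %s: %d taxa with comparable presort abundance but differential IgA targeting",
                  format(age), sum(tg$differentially_targeted)))
}

# plasma-analyte volcano screen on a simulated 387-metabolite panel,
# 9 controls vs 7 celiac, one planted 1.92-fold effect
panel <- simulate_feature_table(387, c(control = 9, celiac = 7),
                                effect_features = 1,
                                effect_log2fc = log2(1.92),
                                seed = stage_seed(seed, "panel"))
v <- volcano_screen(panel$features, panel$metadata)
utils::write.table(v, file.path(out, "volcano.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("volcano: %d/%d analytes above both gates; planted analyte FC estimate %.2f (p<0.05 tally: %d)",
                sum(v$volcano_significant), nrow(v), 2^v$log2fc[1],
                sum(v$p < 0.05)))
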