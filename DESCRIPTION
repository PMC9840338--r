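Package: igaseq
Title: IgA-Seq Coating Index Analysis and Sorted-Fraction Cohort Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of IgA-sequencing (IgA-seq) experiments in which fecal
    bacteria are sorted into IgA-coated (IgA+) and non-coated (IgA-) fractions
    and each fraction is 16S-sequenced. Implements the IgA coating index (ICI)
    with its retention and discordance rules, high-coater calls, and the
    composite screen for taxa of comparable presort abundance that are
    differentially targeted by the mucosal IgA response; permutation-based
    two-group differential abundance with Benjamini-Hochberg correction; a
    volcano screen for plasma analytes; community statistics (observed
    richness, Bray-Curtis dissimilarity, PERMANOVA, PCA, one- and two-way
    ANOVA); and a generative simulator of sorted-fraction sequencing cohorts
    with full ground truth (per-taxon coating probabilities, sorting
    impurity, sequencing depth) for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    stats,
    utils
Suggests:
    biomformat,
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
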