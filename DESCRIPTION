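Package: aimsel
Title: Ancestry-Informative Marker Selection and Admixture Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating panels of ancestry informative
    markers (AIMs) for admixed populations. Scores biallelic SNPs with five
    informativeness statistics (absolute allele-frequency difference, Fst,
    Fisher information content, Shannon information content, and the
    informativeness-for-assignment measure), applies a physical-distance
    filter to produce AIM panels, quantifies inter-measure concordance
    (Spearman correlation, decile-based Cohen's kappa, top-n overlap
    patterns), estimates individual and population admixture proportions by
    maximum likelihood under Hardy-Weinberg equilibrium, and evaluates panels
    by cross-validated discriminant accuracy, bias and RMSE against the
    tracked truth of a forward-time admixture simulator with recombination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    e1071,
    optparse
Config/testthat/edition: 3
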