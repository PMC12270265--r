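Package: grsim
Title: Simulating SNP Genotype Arrays and Genetic Risk Scores from Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates single-nucleotide polymorphism (SNP) genotype arrays
    from summary statistics alone -- per-SNP allele frequencies, pairwise
    dosage correlations, and genotype-class fractions for SNPs deviating
    from Hardy-Weinberg equilibrium -- using a marginal-preserving swap
    optimizer that permutes genotype values within columns until realized
    pairwise correlations match their targets. Computes linear-plus-
    interaction genetic risk scores (GRS) from genotype matrices, and
    provides an evaluation battery (bootstrap distribution summaries,
    ROC/AUC, PCA projections) for comparing simulated against real arrays
    and scores. Includes a Gaussian-copula fixture generator producing
    ground-truth correlated genotype arrays for end-to-end testing, and a
    command-line interface wiring the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    S4Vectors
Config/testthat/edition: 3
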