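Package: poolvar
Title: Pooled Variant Fitness Profiling from Replicate Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of drug-selection timecourses of pooled point-mutation
    libraries ("variomics" pools) profiled by deep amplicon sequencing.
    Provides a seeded simulator of library construction, haploid-viability
    filtering, serial passaging under selection with bottleneck drift, and
    replicate sequencing counts with locus-specific error; a hierarchical
    beta-binomial model fitted by Metropolis-within-Gibbs MCMC to estimate
    per-locus variant allele frequencies with credible intervals; a Bayesian
    posterior-difference (somatic) test with a chi-squared alt-base
    non-uniformity filter to call emergent or depleted variants between
    timepoints; a tanh-transformed Kullback-Leibler pool-diversity score;
    and promoter/CDS/terminator classification with codon-level amino-acid
    effect annotation and timecourse VAF-change matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
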