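Package: poolsel
Title: Divergence and Selection Analysis for Pooled Transcriptomes of Sibling Species
Version: 0.1.0
Authors@R:
    person("poolsel", "maintainers", email = "poolsel@example.org", role = c("aut", "cre"))
Description: Tools to detect signatures of divergent selection between two
    closely related species from pooled RNA-seq data. Classifies sites of
    orthologous open reading frames as fixed interspecific differences or
    within-species polymorphisms using read-count presence rules, estimates
    pairwise dN/dS on fixed-difference codon alignments by maximum likelihood
    under a Goldman-Yang codon substitution model with a likelihood-ratio test
    against neutrality (and a Nei-Gojobori counting estimator as an
    independent check), runs gene-set enrichment statistics (Fisher's exact,
    Mann-Whitney U, goodness-of-fit chi-square, Pearson correlation), builds
    consensus membrane topologies from multiple predictors, maps
    non-synonymous substitutions onto protein domains, and simulates pooled
    read pileups with known ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
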