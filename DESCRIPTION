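Package: mitotempo
Title: Temporal Mitogenome Population Genetics with Ancient and Modern Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing mitochondrial genome diversity between
    heterochronous sample groups (for example ancient-DNA and modern
    collections of a marine fish). Computes haplotype-level summary
    statistics (nucleotide diversity, haplotype diversity, Watterson's
    theta, Tajima's D) under pairwise deletion of missing data, net
    divergence between clades, rarefaction curves, hierarchical AMOVA
    with permutation p-values, a permutation test for diversity change
    between groups, and a bootstrap-subsampled Fisher exact test for
    temporal shifts in clade frequencies. Builds Fitch-parsimony
    haplotype genealogies from a tree plus alignment and assigns major
    clades by cutting long mutational paths. Includes a serial-sampling
    coalescent simulator (two anciently diverged, presently admixed
    clades; post-glacial exponential expansion; two-rate mutation) for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
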