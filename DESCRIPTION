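Package: mirrormap
Title: Linkage Maps from Targeted SNP Capture in Selfed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction of genetic linkage maps for selfed (S1) diploid
    populations genotyped by targeted SNP sequence capture. Provides genotype
    calling from per-marker allele depths, marker and individual quality
    filtering, phase resolution of unphased genotypes via artificial "mirror"
    markers, two-point recombination-fraction and LOD estimation by EM,
    linkage-group formation, marker ordering by obligate-crossover
    minimization with a permuted sliding window, multipoint map estimation
    under a hidden Markov model with genotyping error (Haldane map function),
    and map diagnostics (segregation distortion, crossover screens, Marey
    comparison against a physical assembly). A meiosis and read-count
    simulator generates truth-known populations so every stage can be
    verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
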