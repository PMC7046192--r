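Package: neowsweep
Title: Neo-W Chromosome Sweeps and Male-Killer Co-Transmission Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and population-genomic analysis of a female-limited
    neo-W chromosome spreading by co-transmission with a maternally inherited
    male-killing endosymbiont, as in the African monarch butterfly contact zone.
    Provides a forward-in-time generator of cohorts with ZW inheritance, an
    autosome-W fusion, achiasmatic female meiosis, male immigration and a
    three-allele colour-pattern supergene; sliding-window diversity and
    differentiation scans (pi, dXY, Hudson FST, heterozygosity); quantitative-trait
    Wald association with SNP filtering and thinning; per-window haplotype cluster
    painting of the supergene; diagnostic-site detection and fragment-based haploid
    neo-W reconstruction with moment-based root dating; frequency-stratified Pn/Ps
    with gene bootstrap; and a Procrustes (PACo-style) permutation test of
    host-symbiont genealogical congruence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    broom,
    dplyr,
    GenomicRanges,
    ggplot2,
    IRanges,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
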