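Package: dmtest
Title: Neutrality Tests for Single Methylation Polymorphism Frequency Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects natural selection on heritable DNA methylation from
    population samples of single methylation polymorphisms (SMPs).  Implements
    the Dm site-frequency-spectrum neutrality test, a finite-site two-state
    (Cavender-Farris-Neyman) adaptation of Tajima's D with gamma-distributed
    epimutation rates across cytosine sites, together with the classic Tajima's
    D and a four-state finite-site variant for comparison.  Includes a
    parsimony-based moment estimator of the gamma shape parameter, a coalescent
    simulator of methylation state matrices under neutral, demographic and
    population-epigenetic selection scenarios (deterministic epiallele
    trajectories with a trajectory-conditioned structured coalescent and
    recombination), empirical-null power machinery, and readers for methylation
    state matrices, Illumina 450K beta tables and gene annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    phangorn,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
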