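Package: ychron
Title: Y-Chromosome Haplotree Construction, Calibrated Dating, Phylogeography and Population Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for high-coverage Y-chromosome
    haplogroup studies. Implements region-based variant quality control
    (singleton clusters, replicate discordance, recurrent sites, missingness),
    perfect-phylogeny haplotree construction with ISOGG-style branch naming,
    node-calibrated Bayesian molecular-clock dating with a skyline coalescent
    prior, continuous-space Brownian phylogeography with 2-D HPD summaries,
    derived-allele placement of degraded ancient samples onto the haplotree,
    and Y-STR gene diversity with spatial interpolation surfaces. A coalescent
    simulator with known ground truth (genealogies, mutations, geography,
    STRs, degraded samples, QC artifacts) makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    grDevices,
    MASS,
    jsonlite,
    geosphere,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
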