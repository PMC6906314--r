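Package: introscan
Title: Genome Scans for Ancient Introgression in Four-Taxon Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection, localization and dating of ancient introgression from
    whole-genome variant data of four ingroup species plus an outgroup, with one
    diploid individual per species. Implements site-pattern (ABBA-BABA)
    Patterson's D with block-jackknife significance, a sliding-window f_d
    admixture-proportion scan with candidate-region calling, triplet-based
    detection and molecular-clock dating of introgressed blocks, sliding-window
    heterozygosity, quartet-topology segmentation of the genome, conversion and
    summarization of sequentially Markovian coalescent (MSMC2-format) output,
    and a chi-square gene-set enrichment test for genes in candidate regions.
    Ships a coalescent simulator of four-ingroup-plus-outgroup diploid genomes
    with planted introgression tracts of known age, used for calibration and
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    ape,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
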