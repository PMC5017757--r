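Package: pdxpurity
Title: Mouse Stromal Content Quantitation and Contamination Benchmarks for
    Patient-Derived Xenografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring and modelling mouse DNA contamination in
    patient-derived xenograft (PDX) tumors. Implements species-specific PCR
    amplicon length (ssPAL) quantitation of mouse versus human DNA from
    capillary-electrophoresis fragment traces (peak detection, species
    assignment by amplicon size, area-ratio fraction estimation, dilution
    series, passage-stability and cohort summaries, and a strict mouse-origin
    flag), and an in silico virtual-PDX workbench: synthetic two-species
    genome pairs, read simulation, somatic mutation spike-in at known variant
    allele frequencies, mouse-read contamination, alignment to a concatenated
    human/mouse hybrid reference with a k-mer seed-and-extend aligner,
    coverage profiling, a binomial tumor-versus-normal somatic caller, and
    precision/recall/F1 evaluation across contamination levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
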