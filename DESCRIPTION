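Package: crossld
Title: Linkage Disequilibrium Structure in Crossbred Populations and
    Their Component Pure Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes linkage disequilibrium (LD) in a three-way
    crossbred population and its component pure lines from phased SNP
    genotypes: per-population SNP quality control with a stage-by-stage
    attrition report, pairwise r/r-squared/D' within a distance cap,
    distance-binned LD-decay curves by chromosome category,
    cross-population consistency of LD phase as the binned correlation
    of r, Gabriel-style haploblock detection from D' confidence bounds,
    sliding-window haplotype homozygosity, minor-allele-frequency
    spectra and Weir-Cockerham F_st.  A forward Wright-Fisher simulator
    generates diverged pure lines and their B x [C x D] three-way cross
    with category-specific recombination rates, so the whole pipeline is
    testable without proprietary genotype data, including the in-silico
    prediction of crossbred LD from a weighted pool of pure-line
    haplotypes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
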