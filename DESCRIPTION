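Package: tillersweep
Title: Selective-Sweep Scans and Tiller-Number Association for Rice
    Resequencing Panels
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic selection scans and genotype-phenotype
    association analyses for detecting artificially selected tillering loci
    in rice. Implements windowed Nei FST scans, the population branch
    statistic (PBS) with the Cavalli-Sforza branch-length transform, a
    polymorphism/fixation (HKA-style) chi-square test, derived
    allele-frequency-spectrum diagnostics of hitch-hiking with a
    Kolmogorov-Smirnov distance-decay test, homozygote-group and conditional
    t-test association for tiller number, and segregation-distortion tests
    for biparental crosses. A Balding-Nichols-based synthetic-data generator
    (three diverged populations with an optional local sweep, F8 RIL and
    near-isogenic F2 crosses, additive tiller phenotypes) makes every stage
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
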