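Package: genebin
Title: Gene-Based Multi-Marker Association Tests with LD Binning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based multiple-regression association testing for
    quantitative traits, combining common and low frequency variants.
    Implements joint and marginal regression global statistics (Wald,
    MinP, multi-bin linear combination MLC-B/MLC-Z, LC-B/LC-Z, PC80,
    SSB/SSBw, SKAT and SKAT-C) with linkage-disequilibrium binning by a
    greedy LDSelect-style algorithm, within-bin allele-coding correction,
    mixture-of-chi-square null distributions, omitted-causal-variant
    expected-coefficient theory, and a seeded haplotype-pool simulation
    engine for type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    mvtnorm,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
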