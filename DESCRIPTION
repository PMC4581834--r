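Package: hafscore
Title: Haplotype Allele Frequency Scores and Carrier Prediction in Selective Sweeps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes haplotype allele frequency (HAF) vectors and l-HAF scores
    from phased binary haplotype matrices, together with their theoretical
    expectations under neutral constant-size populations, exponential
    population growth (conditional-expectation epoch times with the
    exponential integral), and ongoing selective sweeps. Includes coalescent
    and forward Wright-Fisher simulators with carrier ground truth, and the
    PreCIOSS algorithm, which clusters l-HAF scores with a two-component
    Gaussian mixture to predict which haplotypes carry the favored allele of
    an ongoing sweep. Readers for ms-style simulator output and phased VCF
    with ancestral-allele polarization are provided.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    mclust,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
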