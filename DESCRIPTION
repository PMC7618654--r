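Package: methfid
Title: Fidelity Analysis of piRNA-Directed Transposon DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies per-locus transposon CpG methylation from
    Bismark-style cytosine reports and discriminates failure modes of de novo
    methylation (uniform inefficiency, deterministic subset failure, stochastic
    per-replicate failure) using family medians and summed across-replicate
    variance. Includes synthetic methylome and nucleus-image generators with
    known ground truth, consensus-scaled metaplots, divergence correlation,
    masked Pearson colocalisation with Costes bisection auto-thresholding and
    block-shuffle randomisation, DAPI-dense heterochromatin overlap
    classification of FISH spots, and an IP-MS enrichment hit filter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    tiff,
    IRanges,
    S4Vectors,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
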