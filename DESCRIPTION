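Package: nucsens
Title: TSS-Anchored Nucleosome Occupancy and MNase Sensitivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of promoter nucleosome organization from paired-end
    micrococcal nuclease (MNase) sequencing of transcription start site
    (TSS)-captured chromatin. Turns mononucleosome fragment intervals from
    light and heavy MNase digests into TSS-anchored fragment-midpoint
    occupancy matrices and log2(light/heavy) MNase-sensitivity matrices,
    sorts and clusters promoters (max-signal quartiles, expression
    quartiles, k-means profile clusters), tests condition-dependent shifts
    in -1 nucleosome sensitivity with paired t-tests, and overlays
    regulatory-factor narrowPeak binding on the same promoter sort orders.
    Includes a synthetic digestion simulator with ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
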