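Package: exoquality
Title: Rank-Based Quality Control for Extracellular Vesicle Isolation Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the expected consistency of extracellular-vesicle (EV)
    isolates across isolation methods from replicated multi-assay
    characterization data. Each measurement set (particle size, concentration,
    total protein, total RNA, particle dispersity index) is placed on a common
    equal-likelihood scale by a rank-based quantile transformation; the
    across-replicate standard deviation of the transformed values, aggregated
    over assays, gives a per-method per-sample EV Inconsistency value (EVI),
    and one minus its average over samples gives the per-method ExoQuality
    Index (EQI). Includes summaries of nanoparticle tracking analysis (NTA)
    size profiles, a seeded simulator of multi-method EV characterization
    studies with known method bias and replicate noise, a parameter-recovery
    harness, ggplot2 visualisations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
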