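Package: epasis
Title: Elution Profile Analysis of SDS-Induced Sub-Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves affinity-purified protein complexes into sub-modules
    from stepwise SDS-destabilization elution experiments read out by
    quantitative mass spectrometry (EPASIS). Builds per-protein cumulative
    relative-abundance elution profiles from replicated intensity tables,
    scores each profile against literature-curated consensus sub-complex
    profiles by elution profile distance (EPD), calibrates the assignment
    threshold by a stepwise sensitivity/specificity search, and classifies
    proteins as reference members, module candidates, or unknown. Includes
    nonmetric multidimensional scaling ordination and replicate
    reproducibility statistics for quality control, affinity-purification
    evidence filters (bait/control replicate rule, unique-peptide rule), the
    significance-A robust outlier statistic for SILAC log-ratios, and a
    seeded synthetic-experiment generator with ground-truth labels for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
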