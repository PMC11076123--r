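Package: protrans
Title: Vertical Transmission Bottlenecks in Termite Gut Protist Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the transmission of a multi-species hindgut protist
    community through the abundance bottleneck that occurs when termite
    alates disperse from the natal colony. Provides a data model for
    haemocytometer cell-count data with volume scale-up, Monte-Carlo
    multinomial resampling of hypothetical alate communities together with
    an exact inclusion-exclusion retention probability, the minimum
    propagule-size (minimum transmitted cells) search, descriptive
    bottleneck statistics (caste abundance summaries, rare-species fold
    enrichment, threshold exceedance, Bray-Curtis dissimilarity, detection
    ratios, cell circularity), a Dirichlet-multinomial synthetic data
    generator calibrated to published caste-level abundances, and a
    reproduction pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
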