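Package: climsuit
Title: Mechanistic Bioclimatic Suitability, Voltinism and Phenology Modelling
    on Gridded Monthly Climate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A CLIMEX-style ecoclimatic niche model for poikilothermic pests,
    parameterised for the brown marmorated stink bug (Halyomorpha halys) and
    designed for high-resolution gridded monthly climatologies of
    topographically complex regions. Weekly temperature, soil-moisture and
    diapause indices are combined into an annual Ecoclimatic Index (EI),
    degree-day voltinism and growth-season phenology; delta-change climate
    scenarios, threshold-based suitability summaries and occurrence-record
    overlap validation reproduce a complete pest risk analysis pipeline.
    A synthetic alpine climate generator stands in for proprietary national
    climatologies so the full pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
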