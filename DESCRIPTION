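Package: soctau
Title: Subsoil Soil Organic Carbon Turnover Times and Their Climate and
    Soil Drivers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates apparent turnover times of soil organic carbon in
    the 0.3-1 m subsoil layer from gridded soil, productivity and climate
    inputs. Carbon stocks are derived from organic-carbon content, bulk
    density and gravel; carbon inputs to the layer are obtained by
    partitioning net primary production with biome-level belowground
    allocation fractions and a logistic dose-response root-depth curve.
    Uncertainty is propagated with a joint Monte-Carlo/bootstrap ensemble,
    and turnover times are attributed to climate versus soil drivers with
    moving-window boosted regression trees, performance-weighted relative
    influence, and a partial-least-squares path model with latent climate
    and soil variables. A synthetic-world generator with known causal
    structure supports end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
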