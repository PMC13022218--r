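Package: wetstage
Title: Two-Stage Random Forest Mapping of Wetland Nutrient Concentrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Spatiotemporal mapping of nitrogen and phosphorus concentrations
    in small wetland systems from sparse in-situ water samples, discrete
    wetland attributes, and Sentinel-1/Sentinel-2 style imagery. A stage-1
    random forest predicts a baseline concentration from discrete per-wetland
    characteristics (morphometrics, land-use composition, short-term climate);
    a stage-2 random forest explains the stage-1 residuals with continuous
    per-pixel satellite-derived predictors (spectral indices, SAR backscatter
    ratios); the two are combined additively by map algebra into quarterly
    per-pixel concentration maps. Includes quarterly mean compositing,
    spectral/SAR index computation, hold-out validation metrics (r2, RMSE,
    MAE, MBE), quarter-averaged variable-importance heatmaps, and a fully
    synthetic study generator with a known additive generative model for
    end-to-end testing.
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
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
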