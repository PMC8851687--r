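Package: adipoScreen
Title: High-Content Screening Pipeline for Adipogenesis Assays of
    Chemical Mixtures
Version: 0.1.0
Authors@R:
    person("Plastics", "Screening Lab", email = "dev@example.org",
           role = c("aut", "cre"))
Description: Tools for plate-based high-content screening of adipocyte
    differentiation in 3T3-L1 cells. Generates synthetic two-channel
    (nuclei / neutral-lipid) field images with known ground truth,
    segments nuclei, cell regions and lipid droplets, classifies single
    cells into preadipocytes, adipocytes and mature adipocytes, computes
    plate-level limits of detection, cytotoxicity gates and
    four-parameter logistic dose-response fits with EC10/EC20
    interpolation, calls multi-endpoint adipogenic activity, analyzes
    tabular reporter-gene plates, and triages nontarget mass-spectrometry
    feature tables against procedure blanks with cross-referencing to a
    curated list of metabolism-disrupting chemicals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
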