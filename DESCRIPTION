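Package: adtiter
Title: Titration Analysis for Oligo-Conjugated Antibody Panels in Droplet Single-Cell Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for optimizing antibody-derived tag (ADT) panels in CITE-seq and
    related droplet single-cell assays. Quantifies ambient-antibody background from
    empty droplets via barcode-rank inflection detection, computes per-antibody
    titration metrics (total UMIs, 90th-percentile signal in the expressing cluster,
    signal-to-noise, background share, cell/empty frequency ratios), classifies each
    antibody's dilution response into five actionable categories with concentration
    recommendations, equalizes conditions by cell-type composition and hypergeometric
    count thinning for fair comparison, and models antibody reagent and sequencing
    costs. Ships a mechanistic droplet simulator (equilibrium antibody binding with
    depletion, shared ambient pool, finite sequencing depth) with ground truth so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    grDevices,
    ggplot2,
    rlang,
    patchwork,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
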