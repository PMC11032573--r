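Package: wmhregions
Title: Regional White Matter Hyperintensity Volumetry and Mixed-Model
    Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Atlas-based regional volumetry of white matter hyperintensities
    (WMH) from template-space binary lesion masks, a vascular risk compound
    score and harmonized amyloid-beta 42 status, and per-region linear mixed
    models with site random intercepts relating each determinant to regional
    WMH volume before and after total-WMH adjustment. Includes a synthetic
    multi-site cohort and 3D lesion simulator with known ground-truth effect
    structure, so the full pipeline is testable without access to patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    lme4,
    yaml,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
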