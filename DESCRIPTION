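Package: radiohet
Title: Intra-Patient Lesion Heterogeneity Analysis for PET Radiomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intra-patient lesion heterogeneity in multi-lesion
    PET cohorts. Extracts a 42-feature radiomic vector (first-order, shape,
    GLCM, GLRLM, NGLDM, GLZLM) from each lesion volume of interest, measures
    within-patient lesion cohesion with silhouette indices under patient-,
    anatomy-, and SUVmax-tertile-based slicings, classifies tumour burden
    under 3- and 5-lesion oligometastatic definitions, screens features with
    nonparametric tests across clinical splits, and characterises unsupervised
    lesion clusters. Includes a synthetic multi-lesion cohort generator with
    controllable within- versus between-patient feature dispersion so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    RNifti,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
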