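Package: marrowquant
Title: Automated Whole-Body Bone-Marrow Metabolic Quantification on FDG PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-based quantification of bone-marrow glucose metabolism
    on whole-body [18F]FDG PET/CT for multiple myeloma. Implements CT-driven
    skeletal segmentation with axial/extremity partition and skull exclusion,
    ten reference-organ and absolute SUV threshold approaches yielding
    metabolic tumor volume (MTV) and total lesion glycolysis (TLG), automated
    IMPeTUs-style reading (Deauville scores, focal and lytic lesion counts,
    paramedullary and extramedullary disease flags), and the downstream
    prognostic statistics (Spearman correlation, Kaplan-Meier, log-rank,
    Cox proportional hazards, ROC with Youden cut points, ISS/R-ISS staging).
    Ships a seeded digital phantom and survival-cohort simulator so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pROC,
    RNifti,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
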