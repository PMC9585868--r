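Package: tsrquant
Title: Tumour-Stroma Ratio Quantification and Prognosis from CK-IHC
    Tissue Microarray Cores
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the tumour-stroma ratio (TSR) from cytokeratin
    immunohistochemistry tissue-microarray core images by hue-channel Otsu
    segmentation with morphological repair, selects a prognostic TSR cutoff
    by maximally selected rank statistics, and evaluates prognosis with
    Pearson chi-square association tables, Kaplan-Meier / log-rank analysis
    and Cox proportional-hazards models (TSR categorical and per-10-percent
    continuous). A synthetic-data module renders TMA-like cores with known
    tumour fraction and simulates breast-cancer-like cohorts with planted
    hazard structure so the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    survival,
    png,
    jsonlite,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
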