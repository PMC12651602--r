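Package: picscore
Title: Rare-Event Detection and Contact-Interface Scoring for Liquid
    Biopsy Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for enrichment-free liquid biopsy slide
    images: simulation of multichannel immunofluorescence slides with
    planted ground truth, detection of circulating tumor cells (CTCs) and
    large extracellular vesicles (LEVs) by standard-deviation intensity
    thresholds and size/brightfield filters, identification of
    tumor-immune neighbor pairs from segmentation masks, quantification
    of membrane-marker enrichment at the white blood cell contact
    interface to separate physiologically interacting clusters (PICs)
    from passive overlaps, imaging-mass-cytometry style phenotyping
    (log-transformed ion counts, hierarchical clustering, immune gating,
    Fisher enrichment), and per-patient per-mL cohort enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
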