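Package: amniolipids
Title: Targeted Amniotic Fluid Lipidomics for Fetal Lung Maturity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted lipidomic analysis of amniotic fluid aimed at
    fetal lung maturity (FLM) prediction. Implements library-based peak
    extraction by accurate mass (ppm tolerance) and retention time, total ion
    count normalization, quality-control replicate precision (CV) and PCA
    assessment, the summed-intensity lecithin/sphingomyelin (L/S) ratio
    classifier and the lamellar body count (LBC) classifier with clinical
    sensitivity/specificity evaluation, biomarker discovery via Welch t-tests,
    fold changes and PLS-DA variable importance (VIP) scores, metabolite-set
    enrichment with Holm-Bonferroni adjustment and pathway topology impact
    scores, and a synthetic-data generator producing gestational-age-structured
    cohorts for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
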