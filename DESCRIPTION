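Package: msiSpatial
Title: Spatial Statistics for Mass Spectrometry Imaging of Pulmonary Drug
    Distribution
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of MALDI mass spectrometry imaging (MSI) data for
    drug-distribution studies in lung tissue sections. Reads and writes
    centroided, processed-mode imzML file pairs; extracts 2D ion-intensity
    maps within m/z tolerance windows; normalizes against a sprayed
    internal standard; derives detection thresholds from drug-free control
    sections; estimates the tissue border from the heme channel with an
    alpha hull; computes quartile-based high-intensity "clump" statistics,
    distance-to-border profiles and colocalization scores; and compares
    treatment groups with exact Wilcoxon rank-sum tests and one-way ANOVA
    reconstructed from summary statistics. A seeded synthetic-cohort
    generator emulates the spatial patterns of surfactant-assisted drug
    delivery for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, grDevices, graphics, xml2,
    jsonlite, mgcv
Suggests: testthat (>= 3.0.0), png, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
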