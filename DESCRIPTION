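Package: furatrack
Title: Correlative Ratiometric Calcium Imaging Analysis of T Cell-APC Conjugates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of dual-channel (340/380 nm) Fura-2
    ratiometric calcium time-lapse imaging of primary T cell-macrophage
    co-cultures. Builds ratio stacks with display mapping, extracts per-track
    calcium traces through circular regions of interest, computes thirteen
    per-cell calcium and motility measures with matched-control selection,
    classifies single-cell calcium signatures (flat, transient, low, high),
    runs PCA and Fisher linear discriminant analysis on the scaled measure
    table, quantifies endogenous marker accumulation and polarization at
    cell-cell interfaces from annotated conjugate images, and reproduces
    conjugate-frequency and ionomycin-normalized calcium readouts from flow
    cytometry event tables. Includes a seeded synthetic-data generator
    (tracks, traces, rendered movies, conjugate images, flow events) with
    known ground truth so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
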