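Package: ivdmcr
Title: Multivariate Curve Resolution of FTIR Images of Intervertebral Disc
    Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of hyperspectral Fourier-transform infrared (FTIR)
    microscopy images of intervertebral disc (IVD) sections. Implements
    Savitzky-Golay second-derivative preprocessing, spectral-statistics
    pixel masking, self-contained multivariate curve resolution by
    alternating least squares (MCR-ALS) with NIPALS or SVD initial
    estimates and soft non-negativity constraints, amide-III tissue maps
    and component/tissue ratio maps, reference-library factor assignment
    with C-O-S peak-position discrimination of proteoglycan populations,
    width-normalized regional abundance gradients, and non-parametric
    (Theil-Sen / Kendall) association of regional parameters with
    degeneration covariates including a log-linear T2* relaxometry fit.
    Ships a synthetic IVD phantom generator with full ground truth for
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
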