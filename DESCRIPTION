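Package: mipath
Title: Tracing Fast Cortical Pathways with Time-Delayed Renyi Mutual Information
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for source-space MEG studies of fast
    inter-regional information transfer. Provides a synthetic-session
    generator with planted lagged couplings among regions of interest,
    current-density-vector (CDV) map containers with quintic spline
    interpolation and maxima localization, combinatorial Student-t
    statistical parametric mapping with all-maps intersection activation
    maps, regional activation curves with circular-statistics principal
    directions and moving-window SNR selection, 6-cycle Morlet wavelet
    scalograms, and time-delayed Renyi mutual information connectivity
    maps with influence-diagram extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
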