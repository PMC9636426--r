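Package: burststage
Title: Transcriptional Bursting Analysis Across Erythroid Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis workflow for quantifying transcriptional bursting
    of nascent-transcription spot traces across erythroid differentiation.
    Cells are staged on a one-dimensional differentiation axis from CD71 and
    Ter119 surface-marker intensities by projection onto empirically defined
    marker-trajectory curves; spot-intensity time series are converted into
    ON/OFF intervals, burst durations, sizes and transcriptional output by
    linear interpolation against an ON threshold; variability is quantified
    by Fano factors, Fano-versus-mean regressions and bootstrap confidence
    intervals; and per-cell bursting behaviour is classified into basal,
    high-ON/high-amplitude and low-ON/high-amplitude regimes via a robust
    LOWESS duration-output curve, its inflection, and a basal-amplitude
    deviation score. A synthetic-data module simulates two-state (telegraph)
    promoter traces, marker trajectories and 3D image stacks with ground
    truth, and an image-quantification module measures spots, markers and
    cell size from such stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    igraph,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
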