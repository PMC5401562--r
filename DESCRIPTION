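Package: trichan
Title: Single-Channel Electrophysiology and Pore Geometry Analysis for
    Trimeric Cation Channels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing single-channel patch-clamp recordings of
    trimeric intracellular cation (TRIC) channels and related multimeric
    channels. Simulates gating of an N-mer of independent monomeric pores
    as an aggregated birth-death Markov chain and renders synthetic
    current traces with realistic acquisition settings (sampling rate,
    Gaussian low-pass filtering, baseline noise). Provides all-points
    amplitude histograms with sum-of-Gaussians decomposition to resolve
    multimeric conductance levels, half-amplitude multi-level
    idealization with dead-time correction, open-probability (NPo) and
    dwell-time statistics, linear current-voltage fitting, and
    Goldman-Hodgkin-Katz bi-ionic selectivity analysis. A structural
    module measures transmembrane-helix tilt angles against the trimer
    three-fold axis and classifies pore-radius profiles into
    constriction, intermediate and wide zones.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
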