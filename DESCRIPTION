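Package: rewirescreen
Title: Simulation and Analysis of Transcriptional Rewiring Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combinatorial promoter::CDS rewiring-library screens in
    yeast: simulation of plate-based screens with planted enhancer constructs
    and realistic plate, growth and well noise; the growth-normalisation,
    per-plate standardisation and multi-round outlier hit-calling pipeline;
    fold-change and paired t-test validation statistics; from-scratch directed
    graph topology metrics (out-degree, Brandes betweenness centrality,
    clustering coefficient, eccentricity, regulatory hierarchy levels); and
    one-tailed Welch enrichment tests comparing hit regulators against the
    transcription-factor background of a regulatory network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
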