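Package: circlemap
Title: Circle-Based Conduction Velocity and Voltage Amplitude Analysis for
    High-Density Electroanatomic Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-density electroanatomic maps of the
    cardiac chambers with the circle strategy: triangulated chamber surfaces
    carrying per-vertex local activation times and unipolar voltage
    amplitudes are covered with 5-mm-radius spherical filters, and one
    conduction velocity (theoretical diameter over first-to-last activation
    time) and one mean voltage amplitude are computed per circle.  Includes
    a synthetic chamber-map generator with wavefront simulation on
    triangulated meshes (planar and focal Dijkstra sources), heart-rate and
    pacing-site effects with per-animal random intercepts; linear
    mixed-effects models of log conduction velocity and voltage amplitude
    with marginal means at a reference heart rate and adjusted paced-versus-
    sinus contrasts; and paired-map absolute and relative difference
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    emmeans,
    ggplot2,
    igraph,
    lme4,
    lmerTest,
    stats,
    tools,
    utils,
    grDevices,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
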