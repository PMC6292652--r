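Package: neurowaves
Title: Detection and Analysis of Spatiotemporal Wave Patterns in Neural
    Population Recordings
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting and analysing propagating wave patterns
    (plane waves, synchrony, sources, sinks, spirals and saddles) in
    population-level neural recordings such as multi-electrode LFP grids and
    optical voltage imaging movies.  Band-limited oscillations are reduced to
    amplitude and phase via Butterworth/Hilbert or complex Morlet filtering;
    velocity vector fields are estimated with a Charbonnier-penalised
    variational optical-flow solver with phase-aware circular derivatives;
    patterns are located and classified through critical-point analysis
    (Jacobian trace and determinant), winding numbers and order parameters,
    then linked over time into persistent pattern instances with transition
    statistics.  Dominant spatiotemporal modes are extracted by real or
    complex singular value decomposition of the stacked velocity fields.  A
    synthetic-pattern simulator and white-noise surrogate generator make the
    full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    rhdf5,
    yaml,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
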