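Package: cfhier
Title: Connective Field Modeling and Convergence Along the Visual Hierarchy
Version: 1.0.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Fits circular Gaussian connective fields (CFs) on the cortical
    surface between V1 and extrastriate visual areas in both directions,
    summarises variance-explained-weighted sampling extents, computes the
    convergence magnitude (forward minus backward sampling extent) and its
    slope along the visual hierarchy, and performs exact small-sample
    Wilcoxon rank-sum and signed-rank inference. Includes a synthetic
    retinotopic-cortex generator (flat triangulated patches, drifting-bar
    pRF forward model, direction-specific Gaussian coupling kernels,
    stimulus and resting-state BOLD runs) so the full pipeline is testable
    against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
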