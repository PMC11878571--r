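Package: longconn
Title: Longitudinal Structural Connectome Analysis with Normative Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal analysis of weighted structural
    connectomes built from streamline tractography. Computes global and
    nodal graph metrics (strength, transitivity, modularity, efficiency,
    participation coefficient, eigenvector centrality) and linear network
    controllability measures (average and modal controllability), fits
    age- and sex-adjusted normative models on a control cohort to express
    patient deviations as Z-scores, quantifies abnormal-node burden,
    profiles thalamocortical connectivity per ipsilateral lobe, and runs
    paired non-parametric longitudinal statistics with effect sizes and
    multi-scale sensitivity sweeps. Includes a synthetic cohort generator
    with injectable ground-truth effects so the full pipeline can be
    exercised and calibrated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
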