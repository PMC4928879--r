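Package: emgmm
Title: Gaussian Mixture Modeling of Cyclic Surface EMG During Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring cyclic surface electromyography (sEMG)
    recordings from locomotion trials. Trials are segmented into gait cycles
    using synchronized hoof-marker kinematics, cycles are time- and
    amplitude-normalized, and the recurring activation peaks of each sensor
    are summarized by a multi-modal bivariate Gaussian mixture model fitted
    by expectation maximization with mean-curve-based initialization.
    Includes closed-form Cauchy-Schwarz distances between mixtures,
    intra- and inter-subject variability statistics, agglomerative
    single-linkage exploration of subjects from mixture-derived features,
    and a synthetic trial generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
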