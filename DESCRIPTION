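Package: motorprim
Title: Trial-by-Trial Motor Adaptation Models with Motor Primitives and Effort Minimization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates trial-by-trial motor adaptation to force-field or
    visuomotor perturbations with three learning models: a Gaussian
    motor-primitive framework with weight decay, a scalar state-space model
    with effort minimization, and a motor-primitive framework with effort
    minimization. Provides deterministic error-clamp protocols for probing
    generalization and context-dependent memory decay, seeded multi-run
    ensembles, command-space recursion oracles, analytic fixed points, and
    summary statistics (learning curves, generalization and normalized decay
    functions, retest divergence, and a signal-dependent-noise error
    decomposition).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
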