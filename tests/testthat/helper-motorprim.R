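# shared fixtures, all generated in code

# minimal two-unit basis used for hand-evaluated oracles
two_unit_basis <- function(sigma = pi / 4) {
  primitive_basis(c(0, pi / 2), sigma = sigma)
}

# a constant-direction training protocol built through the config loader
constant_training_protocol <- function(n_trials, theta = 0, p = pi / 4) {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "name: constant-training",
    "phases:",
    sprintf("  - {label: training, n_trials: %d, theta: %.17g, p: %.17g, clamp: false}",
            n_trials, theta, p)), cfg)
  on.exit(unlink(cfg))
  load_protocol(cfg)
}

# normalized self-overlap G(theta, theta) / N of a basis
ghat_self <- function(basis, theta = 0) {
  generalization_empirical(basis, theta, theta) / basis$n_primitives
}

standard_sim1_directions <- c(0, pi / 12, pi / 6, pi / 4)
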