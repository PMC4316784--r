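test_that("learning curve matches the geometric closed form for pure error correction", {
  # state-space model with lambda2 = 0 at a single direction: e_t = p (1 - eta)^t
  pars <- learner_params(eta = 0.04)
  prot <- constant_training_protocol(200)
  ens <- run_ensemble("state_space_effort", pars,
                      protocol_builder = function(s) prot, n_runs = 2, base_seed = 1)
  lc <- learning_curve(ens)
  expect_equal(lc$mean_error, (pi / 4) * (1 - 0.04)^(0:199), tolerance = 1e-12)
  expect_equal(max(lc$sd_error), 0)  # deterministic model: no across-run spread
  expect_error(learning_curve(list()), "run_ensemble")
})

test_that("the three standard models produce similar learning curves", {
  prot <- constant_training_protocol(120)
  errs <- lapply(c("weight_decay_primitive", "effort_primitive", "state_space_effort"),
                 function(mk) run_simulation(mk, protocol = prot,
                                             basis_seed = 7)$records$error)
  late <- sapply(errs, function(e) mean(abs(e[51:120])))
  # after trial 50 all three have settled near their (similar) asymptotic errors
  expect_true(all(abs(outer(late, late, "-")) < 0.1 * pi / 4))
})

test_that("generalization function peaks at the trained direction and averages test commands", {
  prot <- build_simulation2(8, seed = 4)
  tr <- run_simulation("effort_primitive", protocol = prot, basis_seed = 9)
  g <- generalization_function(tr)
  expect_equal(nrow(g), 8)
  expect_equal(g$direction[which.max(g$value)], 0)
  # n_average = 1 keeps only the first, decay-free test command of each cycle
  g1 <- generalization_function(tr, n_average = 1)
  rec <- tr$records
  first_cmd <- vapply(0:7, function(cc)
    rec$x_at_theta_t[rec$phase == "test" & rec$cycle == cc][1], numeric(1))
  dirs <- vapply(0:7, function(cc)
    rec$theta_t[rec$phase == "test" & rec$cycle == cc][1], numeric(1))
  expect_equal(g1$value[order(g1$direction)], first_cmd[order(dirs)])
  # a protocol without cycles cannot be summarized
  tr1 <- run_simulation("effort_primitive", protocol = build_simulation1(0),
                        basis_seed = 9)
  expect_error(generalization_function(tr1), "cycles")
})

test_that("state-space generalization is zero off the trained direction", {
  tr <- run_simulation("state_space_effort", protocol = build_simulation2(8, seed = 4))
  g <- generalization_function(tr)
  expect_true(all(g$value[g$direction != 0] == 0))
  expect_gt(g$value[g$direction == 0], 0.5)
})

test_that("decay function is normalized, bounded, and context dependent only for effort", {
  prot <- build_simulation2(16, seed = 6)
  eff <- decay_function(run_simulation("effort_primitive", protocol = prot,
                                       basis_seed = 2))
  expect_true(all(eff$value > 0 & eff$value < 1.02))
  wd_tr <- run_simulation("weight_decay_primitive", protocol = prot, basis_seed = 2)
  wd <- decay_function(wd_tr)
  # weight decay: all cycles after the first are equal to machine precision,
  # and the whole profile is flat to the first-cycle convergence transient
  rec <- wd_tr$records
  x0 <- rec$x_at_theta_t[rec$phase == "training"][200]
  per_cycle <- vapply(0:15, function(cc)
    mean(rec$x_at_theta_t[rec$phase == "relearning" & rec$cycle == cc][1:10]) / x0,
    numeric(1))
  expect_lt(diff(range(per_cycle[-1])), 1e-10)
  expect_lt(diff(range(wd$value)), 1e-6)
  # effort decays most where tested closest to the trained direction (ensemble mean)
  ens <- run_ensemble("effort_primitive",
                      protocol_builder = function(s) build_simulation2(16, seed = s),
                      n_runs = 10, base_seed = 8)
  d <- decay_function(ens)
  expect_equal(d$direction[which.min(d$mean)], 0)
  expect_gt(mean(d$mean[abs(d$direction) > 2]), d$mean[d$direction == 0])
})

test_that("effort decay with a tiny tuning width spares fully non-overlapping directions", {
  # sigma small: clamp trials at the opposite direction do not touch x(0),
  # clamp trials at the trained direction erode it
  prot <- build_simulation1(-pi)
  tr <- run_simulation("effort_primitive", protocol = prot, basis_seed = 3,
                       sigma = 0.05, probe_grid = 0)
  x0_probe <- tr$probes[, 1]
  expect_equal(x0_probe[201], x0_probe[101], tolerance = 1e-9)  # maintained
  tr0 <- run_simulation("effort_primitive", protocol = build_simulation1(0),
                        basis_seed = 3, sigma = 0.05, probe_grid = 0)
  expect_lt(tr0$probes[201, 1], tr0$probes[101, 1] - 1e-3)      # eroded
})

test_that("retest divergence separates context-dependent from independent decay", {
  traces <- function(mk) lapply(standard_sim1_directions, function(tt)
    run_simulation(mk, protocol = build_simulation1(tt), basis_seed = 4))
  wd <- retest_divergence(traces("weight_decay_primitive"))
  expect_lt(diff(range(wd$retest_x)), 1e-12)          # all equal: context independent
  ef <- retest_divergence(traces("effort_primitive"))
  expect_true(all(diff(ef$retest_x) > 0))             # increasing with |theta_test|
  # mismatched seeds are rejected
  bad <- list(run_simulation("effort_primitive", protocol = build_simulation1(0),
                             basis_seed = 1),
              run_simulation("effort_primitive", protocol = build_simulation1(pi / 6),
                             basis_seed = 2))
  expect_error(retest_divergence(bad), "share")
})

test_that("noise decomposition is exact and minimized at the effort fixed point", {
  d <- noise_error_decomposition(1, 0.8, 0.06)
  expect_equal(d$constant_error, 0.04)
  expect_equal(d$variable_error, 0.0384)
  expect_equal(d$mean_squared_error, 0.0784)
  expect_equal(noise_error_decomposition(1, 0, 0.5)$variable_error, 0)
  expect_error(noise_error_decomposition(1, 1, -0.1), "non-negative")
  # quadratic in x: the vertex of the parabola through three evaluations
  # recovers p / (1 + lambda2)
  p <- pi / 4; l2 <- 0.06
  f <- function(x) noise_error_decomposition(p, x, l2)$mean_squared_error
  xs <- c(0, 0.5, 1)
  fs <- vapply(xs, f, numeric(1))
  co <- solve(cbind(1, xs, xs^2), fs)
  vertex <- unname(-co[2] / (2 * co[3]))
  expect_equal(vertex, fixed_point_command(p, learner_params(0.5, lambda2 = l2),
                                           "effort_primitive"), tolerance = 1e-12)
})
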