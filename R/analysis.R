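#' Ensemble learning curve
#'
#' Per-trial mean and standard deviation of the movement error across the
#' runs of an ensemble.
#'
#' @param ensemble a `run_ensemble`.
#' @return data.frame with columns index, phase, cycle, mean_error, sd_error.
#' @export
learning_curve <- function(ensemble) {
  if (!inherits(ensemble, "run_ensemble")) stop("'ensemble' must be a run_ensemble", call. = FALSE)
  ensemble$summary[, c("index", "phase", "cycle", "mean_error", "sd_error")]
}

# per-cycle summaries of a single trace; f maps the block rows to a scalar
cycle_values <- function(trace, phase, n_average, value_phase = phase) {
  rec <- trace$records
  cyc <- sort(unique(rec$cycle[rec$phase == phase & !is.na(rec$cycle)]))
  if (length(cyc) == 0L) {
    stop(sprintf("trace has no '%s' cycles (need an alternating-design protocol)", phase),
         call. = FALSE)
  }
  direction <- vapply(cyc, function(cc) {
    rec$theta_t[rec$phase == "test" & rec$cycle %in% cc][1L]
  }, numeric(1))
  value <- vapply(cyc, function(cc) {
    rows <- rec[rec$phase == value_phase & rec$cycle %in% cc, , drop = FALSE]
    mean(utils::head(rows$x_at_theta_t, n_average))
  }, numeric(1))
  data.frame(cycle = cyc, direction = direction, value = value)
}

aggregate_runs <- function(per_run) {
  # per_run: list of data.frames (direction, value); directions shared across runs
  dirs <- sort(unique(per_run[[1L]]$direction))
  vals <- vapply(per_run, function(df) df$value[match(dirs, df$direction)],
                 numeric(length(dirs)))
  vals <- matrix(vals, nrow = length(dirs))
  data.frame(direction = dirs, mean = rowMeans(vals),
             sd = apply(vals, 1L, stats::sd))
}

#' Generalization function from an alternating-design run
#'
#' For each cycle of an alternating test/relearning design, averages the
#' executed command over the first `n_average` error-clamp test trials at
#' that cycle's direction theta'. Plotting the result against theta' gives
#' the empirical generalization function: how much of the command learned at
#' theta = 0 is expressed at each tested direction. Early-trial averaging
#' limits contamination by within-block decay.
#'
#' @param x a `simulation_trace` or a `run_ensemble` built on an
#'   alternating-design protocol (see [build_simulation2()]).
#' @param n_average number of initial test trials to average (default 10).
#' @return data.frame with columns `direction` and `value` (single trace) or
#'   `direction`, `mean`, `sd` (ensemble).
#' @export
generalization_function <- function(x, n_average = 10L) {
  if (inherits(x, "simulation_trace")) {
    return(cycle_values(x, "test", n_average)[, c("direction", "value")])
  }
  if (inherits(x, "run_ensemble")) {
    per_run <- lapply(x$traces, function(tr)
      cycle_values(tr, "test", n_average)[, c("direction", "value")])
    return(aggregate_runs(per_run))
  }
  stop("'x' must be a simulation_trace or run_ensemble", call. = FALSE)
}

#' Normalized context-dependent decay function
#'
#' For each cycle (tested direction theta'), averages the command at the
#' trained direction over the first `n_average` relearning trials and
#' divides by x0, the executed command on the final training trial. Values
#' near 1 mean the memory at theta = 0 survived the test block; a dip at
#' theta' = 0 is the signature of context-dependent decay (testing at the
#' trained direction erodes the memory fastest), while a flat profile means
#' decay was context independent.
#'
#' @inheritParams generalization_function
#' @return data.frame as in [generalization_function()], values
#'   dimensionless.
#' @export
decay_function <- function(x, n_average = 10L) {
  one <- function(trace) {
    rec <- trace$records
    train <- rec[rec$phase == "training", , drop = FALSE]
    if (nrow(train) == 0L) stop("protocol has no training phase", call. = FALSE)
    x0 <- train$x_at_theta_t[nrow(train)]
    if (x0 == 0) stop("degenerate normalization: end-of-training command is 0", call. = FALSE)
    out <- cycle_values(trace, "test", n_average, value_phase = "relearning")
    out$value <- out$value / x0
    out[, c("direction", "value")]
  }
  if (inherits(x, "simulation_trace")) return(one(x))
  if (inherits(x, "run_ensemble")) return(aggregate_runs(lapply(x$traces, one)))
  stop("'x' must be a simulation_trace or run_ensemble", call. = FALSE)
}

#' Retest command level by test-phase direction
#'
#' Given one single-test-direction trace per tested direction (all sharing
#' the same model, parameters and basis seed), averages the command at the
#' trained direction over the first `n_average` retest trials. Divergence of
#' these levels across test directions is the signature of context-dependent
#' memory decay; equality (machine-precision spread) is the signature of
#' context-independent decay.
#'
#' @param traces list of `simulation_trace` objects from
#'   [build_simulation1()] protocols with different `theta_test`.
#' @param n_average number of initial retest trials to average (default 10).
#' @return data.frame with columns `theta_test` and `retest_x`, ordered by
#'   the absolute (circular) test direction.
#' @export
retest_divergence <- function(traces, n_average = 10L) {
  if (!is.list(traces) || length(traces) == 0L ||
      !all(vapply(traces, inherits, logical(1), "simulation_trace"))) {
    stop("'traces' must be a non-empty list of simulation_trace objects", call. = FALSE)
  }
  seeds <- vapply(traces, function(tr) tr$basis_seed, integer(1))
  kinds <- vapply(traces, function(tr) tr$model_kind, character(1))
  if (length(unique(seeds)) != 1L || length(unique(kinds)) != 1L) {
    stop("all traces must share the basis seed and model kind", call. = FALSE)
  }
  theta_test <- vapply(traces, function(tr) {
    th <- unique(tr$records$theta_t[tr$records$phase == "test"])
    if (length(th) != 1L) stop("each trace must have a single test direction", call. = FALSE)
    th
  }, numeric(1))
  retest_x <- vapply(traces, function(tr) {
    rows <- tr$records[tr$records$phase == "retest", , drop = FALSE]
    if (nrow(rows) == 0L) stop("trace has no retest phase", call. = FALSE)
    mean(utils::head(rows$x_at_theta_t, n_average))
  }, numeric(1))
  out <- data.frame(theta_test = theta_test, retest_x = retest_x)
  out[order(abs(wrap_angle(out$theta_test))), , drop = FALSE]
}

#' Signal-dependent-noise decomposition of the mean squared error
#'
#' Under signal-dependent motor noise with variance lambda2 * x^2, the mean
#' squared movement error splits into a constant (bias) part and a variable
#' part:
#' \deqn{\langle e^2 \rangle = (p - x)^2 + \lambda_2 x^2.}
#' Minimizing this over x links effort minimization to noise reduction: the
#' minimizer is the effort models' training asymptote p / (1 + lambda2).
#'
#' @param p perturbation magnitude.
#' @param x noiseless motor command.
#' @param lambda2 signal-dependent-noise coefficient (>= 0).
#' @return list with `constant_error`, `variable_error` and
#'   `mean_squared_error`.
#' @examples
#' noise_error_decomposition(1, 0.8, 0.06)
#' @export
noise_error_decomposition <- function(p, x, lambda2) {
  if (!all(is.finite(c(p, x, lambda2)))) stop("inputs must be finite", call. = FALSE)
  if (lambda2 < 0) stop("'lambda2' must be non-negative", call. = FALSE)
  constant <- (p - x)^2
  variable <- lambda2 * x^2
  list(constant_error = constant, variable_error = variable,
       mean_squared_error = constant + variable)
}
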