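#' Run one simulation of a protocol
#'
#' Executes the per-trial loop shared by all three models. Starting from a
#' zero state, each trial (i) evaluates the command x at the trial's target
#' direction from the current state, (ii) records the movement error
#' e = p - x, forced to 0 on error-clamp trials, (iii) records the command
#' profile on the probe grid (before any update, so the recorded profile is
#' the one that generated the trial's movement), and (iv) updates the state.
#' The state persists across phases with no resets.
#'
#' For the primitive models the state is the weight vector and updates follow
#' [update_weights()]; for the state-space model the state is a single
#' scalar command updated by [update_state_space()] on every trial. The
#' state-space model carries no generalization machinery: its command is
#' expressed only at the trained direction (the direction of the first
#' unclamped trial) and reads as 0 elsewhere, while its memory still decays
#' on every trial.
#'
#' @param model_kind `"weight_decay_primitive"`, `"effort_primitive"` or
#'   `"state_space_effort"`.
#' @param params a `learner_params`; default [default_params()] of the model
#'   kind.
#' @param protocol a `motor_protocol`.
#' @param basis_seed integer seed for the preferred directions (ignored by
#'   the state-space model).
#' @param n_primitives basis size N (default 100).
#' @param sigma tuning width in radians (default pi/4).
#' @param probe_grid optional numeric vector of probe directions at which
#'   the command profile is recorded each trial.
#' @return an object of class `simulation_trace`: list with `records` (one
#'   row per trial: index, phase, cycle, theta_t, p, clamp, error,
#'   x_at_theta_t), `probes` (trial x probe-angle matrix, or NULL),
#'   `probe_grid`, `model_kind`, `params`, `basis` (NULL for state space),
#'   `basis_seed`, `protocol_name` and `final_state`.
#' @export
run_simulation <- function(model_kind, params = default_params(model_kind),
                           protocol, basis_seed = 1L, n_primitives = 100L,
                           sigma = pi / 4, probe_grid = NULL) {
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  if (!inherits(protocol, "motor_protocol")) {
    stop("'protocol' must be a motor_protocol", call. = FALSE)
  }
  if (!inherits(params, "learner_params")) stop("'params' must be learner_params", call. = FALSE)
  n_trials <- nrow(protocol)
  if (n_trials == 0L) stop("empty protocol", call. = FALSE)
  if (!is.null(probe_grid)) {
    if (!is.numeric(probe_grid) || length(probe_grid) == 0L || any(!is.finite(probe_grid))) {
      stop("'probe_grid' must be a non-empty finite numeric vector", call. = FALSE)
    }
  }

  primitive <- model_kind != "state_space_effort"
  basis <- if (primitive) sample_basis(n_primitives, sigma, basis_seed) else NULL

  theta <- protocol$theta
  perturb <- protocol$p
  clamp <- protocol$clamp
  unclamped <- which(!clamp)
  trained_direction <- wrap_angle(theta[if (length(unclamped)) unclamped[1L] else 1L])

  # cache activities per distinct target direction
  if (primitive) {
    theta_key <- match(theta, unique(theta))
    act <- lapply(unique(theta), function(th) activities(basis, th))
    eta_n <- params$eta / basis$n_primitives
    decay1 <- 1 - params$eta * params$lambda1
    W <- numeric(basis$n_primitives)
    probe_act <- if (!is.null(probe_grid)) {
      do.call(rbind, lapply(probe_grid, function(th) activities(basis, th)))
    }
  } else {
    x_state <- 0
    gate <- if (!is.null(probe_grid)) {
      as.numeric(abs(wrap_angle(probe_grid - trained_direction)) < 1e-12)
    }
  }

  err <- numeric(n_trials)
  x_exec <- numeric(n_trials)
  probes <- if (!is.null(probe_grid)) {
    matrix(NA_real_, n_trials, length(probe_grid),
           dimnames = list(NULL, format_angle(probe_grid)))
  }

  for (t in seq_len(n_trials)) {
    if (primitive) {
      a <- act[[theta_key[t]]]
      x <- sum(W * a)
      if (!is.null(probe_grid)) probes[t, ] <- as.vector(probe_act %*% W)
    } else {
      on_trained <- abs(wrap_angle(theta[t] - trained_direction)) < 1e-12
      x <- if (on_trained) x_state else 0
      if (!is.null(probe_grid)) probes[t, ] <- gate * x_state
    }
    e <- if (clamp[t]) 0 else perturb[t] - x
    err[t] <- e
    x_exec[t] <- x
    if (primitive) {
      W <- decay1 * W + eta_n * (e - params$lambda2 * x) * a
    } else {
      x_state <- (1 - params$eta * params$lambda2) * x_state + params$eta * e
    }
  }

  records <- data.frame(index = protocol$index, phase = protocol$phase,
                        cycle = protocol$cycle, theta_t = theta, p = perturb,
                        clamp = clamp, error = err, x_at_theta_t = x_exec)
  structure(list(records = records, probes = probes, probe_grid = probe_grid,
                 model_kind = model_kind, params = params, basis = basis,
                 basis_seed = as.integer(basis_seed),
                 n_primitives = if (primitive) basis$n_primitives else NA_integer_,
                 sigma = if (primitive) basis$sigma else NA_real_,
                 trained_direction = trained_direction,
                 protocol_name = attr(protocol, "name"),
                 final_state = if (primitive) W else x_state),
            class = "simulation_trace")
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat(sprintf("simulation_trace: %s on '%s' (%d trials%s)\n", x$model_kind,
              x$protocol_name, nrow(x$records),
              if (!is.null(x$probes)) sprintf(", %d probe angles", ncol(x$probes)) else ""))
  invisible(x)
}

#' Run a protocol purely in command space (recursion oracle)
#'
#' Independent re-derivation of a primitive-model simulation that never
#' touches the weight vector: it tracks x_t(theta) on the union of the probe
#' grid and the protocol's target directions and advances it with
#' [recursive_command_update()]. Exact agreement with [run_simulation()] is
#' an algebraic identity; the pair is used as a dual-route consistency check.
#'
#' @inheritParams run_simulation
#' @param basis the `primitive_basis` to share with the weight-space run.
#' @return list with `records` (index, error, x_at_theta_t) and `commands`
#'   (trial x tracked-angle matrix of pre-update commands, columns keyed by
#'   [format_angle()]).
#' @export
run_recursion <- function(params, protocol, basis, probe_grid = NULL) {
  stopifnot_basis(basis)
  if (!inherits(protocol, "motor_protocol")) {
    stop("'protocol' must be a motor_protocol", call. = FALSE)
  }
  angles <- unique(wrap_angle(c(protocol$theta, if (!is.null(probe_grid)) probe_grid)))
  xs <- stats::setNames(numeric(length(angles)), format_angle(angles))
  n_trials <- nrow(protocol)
  commands <- matrix(NA_real_, n_trials, length(xs), dimnames = list(NULL, names(xs)))
  err <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    commands[t, ] <- xs
    key <- format_angle(wrap_angle(protocol$theta[t]))
    e <- if (protocol$clamp[t]) 0 else protocol$p[t] - xs[[key]]
    err[t] <- e
    xs <- recursive_command_update(xs, basis, wrap_angle(protocol$theta[t]), e, params)
  }
  list(records = data.frame(index = protocol$index, error = err,
                            x_at_theta_t = commands[cbind(seq_len(n_trials),
                              match(format_angle(wrap_angle(protocol$theta)), colnames(commands)))]),
       commands = commands)
}

#' Evaluate the command profile on a grid without updating the state
#'
#' @param state weight vector (primitive models) as held in a trace's
#'   `final_state`, or the scalar command for the state-space model.
#' @param basis a `primitive_basis`, or NULL for the state-space model.
#' @param probe_grid numeric vector of probe directions (non-empty).
#' @param trained_direction for the state-space model, the direction at
#'   which the scalar command is expressed (default 0).
#' @return named numeric vector of commands keyed by [format_angle()].
#' @export
probe_commands <- function(state, basis, probe_grid, trained_direction = 0) {
  if (!is.numeric(probe_grid) || length(probe_grid) == 0L || any(!is.finite(probe_grid))) {
    stop("'probe_grid' must be a non-empty finite numeric vector", call. = FALSE)
  }
  out <- if (is.null(basis)) {
    as.numeric(abs(wrap_angle(probe_grid - trained_direction)) < 1e-12) * state
  } else {
    vapply(probe_grid, function(th) motor_command(state, basis, th), numeric(1))
  }
  stats::setNames(out, format_angle(probe_grid))
}

#' Derive a per-run seed from a base seed
#'
#' Deterministic splitting rule used by [run_ensemble()]: stream `k` of base
#' seed `base` is `(base * 1000003 + k) mod (2^31 - 1)`, computed in double
#' precision (exact for base seeds below 2^31).
#'
#' @param base integer base seed.
#' @param k stream index (>= 0).
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(base, k) {
  as.integer((as.double(base) * 1000003 + as.double(k)) %% 2147483647)
}

#' Run a seeded ensemble of simulations
#'
#' Repeats a simulation `n_runs` times with independently derived seeds for
#' the basis preferred directions and for the protocol builder (so designs
#' with randomized direction orders re-draw the order per run), and
#' summarizes the per-trial error and executed command across runs. Per-run
#' variability comes solely from this resampling; no observation noise is
#' added.
#'
#' @inheritParams run_simulation
#' @param protocol_builder function of one integer argument (a derived seed)
#'   returning a `motor_protocol`. For deterministic designs ignore the
#'   argument, e.g. `function(seed) build_simulation1(pi/4)`.
#' @param n_runs number of runs (>= 1; 20 in the standard design).
#' @param base_seed integer base seed; run r uses [derive_seed()] streams
#'   `2r - 1` (basis) and `2r` (protocol).
#' @return an object of class `run_ensemble`: list with `traces` (list of
#'   `simulation_trace`), and `summary` (data.frame per trial: index, phase,
#'   cycle, theta_t, mean_error, sd_error, mean_x, sd_x; SDs use the n-1
#'   denominator and are NA for a single run).
#' @export
run_ensemble <- function(model_kind, params = default_params(model_kind),
                         protocol_builder, n_runs = 20L, base_seed = 1L,
                         n_primitives = 100L, sigma = pi / 4, probe_grid = NULL) {
  if (!is.numeric(n_runs) || length(n_runs) != 1L || n_runs < 1 ||
      n_runs != as.integer(n_runs)) {
    stop("'n_runs' must be a positive integer", call. = FALSE)
  }
  if (!is.function(protocol_builder)) stop("'protocol_builder' must be a function", call. = FALSE)
  traces <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    prot <- protocol_builder(derive_seed(base_seed, 2L * r))
    traces[[r]] <- run_simulation(model_kind, params, prot,
                                  basis_seed = derive_seed(base_seed, 2L * r - 1L),
                                  n_primitives = n_primitives, sigma = sigma,
                                  probe_grid = probe_grid)
  }
  n_trials <- vapply(traces, function(tr) nrow(tr$records), integer(1))
  if (length(unique(n_trials)) != 1L) {
    stop("all runs must share the protocol length", call. = FALSE)
  }
  err_mat <- vapply(traces, function(tr) tr$records$error, numeric(n_trials[1]))
  x_mat <- vapply(traces, function(tr) tr$records$x_at_theta_t, numeric(n_trials[1]))
  first <- traces[[1L]]$records
  summary <- data.frame(index = first$index, phase = first$phase, cycle = first$cycle,
                        mean_error = rowMeans(err_mat),
                        sd_error = apply(err_mat, 1L, stats::sd),
                        mean_x = rowMeans(x_mat),
                        sd_x = apply(x_mat, 1L, stats::sd))
  structure(list(traces = traces, summary = summary, model_kind = model_kind,
                 params = params, n_runs = as.integer(n_runs),
                 base_seed = as.integer(base_seed)),
            class = "run_ensemble")
}

#' @export
print.run_ensemble <- function(x, ...) {
  cat(sprintf("run_ensemble: %d runs of %s on '%s' (base seed %d)\n",
              x$n_runs, x$model_kind, x$traces[[1L]]$protocol_name, x$base_seed))
  invisible(x)
}
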