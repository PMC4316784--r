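#' Learning-rule parameters
#'
#' Bundles the learning rate and the two regularization weights of the
#' trial-by-trial cost function
#' \deqn{E_t = \tfrac12 e_t^2 + \tfrac{\lambda_1}{2}\sum_i W_{i,t}^2
#'   + \tfrac{\lambda_2}{2} x_t^2,}
#' i.e. squared movement error plus a weight-magnitude penalty (lambda1,
#' "weight decay") plus a command-magnitude penalty (lambda2, "effort").
#'
#' @param eta learning rate (> 0).
#' @param lambda1 weight-decay regularizer (>= 0).
#' @param lambda2 effort regularizer (>= 0).
#' @return an object of class `learner_params`.
#' @seealso [default_params()] for the standard parameter sets of each model.
#' @export
learner_params <- function(eta, lambda1 = 0, lambda2 = 0) {
  for (nm in c("eta", "lambda1", "lambda2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("'%s' must be a finite scalar", nm), call. = FALSE)
    }
  }
  if (eta <= 0) stop("'eta' must be positive", call. = FALSE)
  if (lambda1 < 0 || lambda2 < 0) stop("regularizers must be non-negative", call. = FALSE)
  structure(list(eta = eta, lambda1 = lambda1, lambda2 = lambda2),
            class = "learner_params")
}

#' @export
print.learner_params <- function(x, ...) {
  cat(sprintf("learner_params: eta = %g, lambda1 = %g, lambda2 = %g\n",
              x$eta, x$lambda1, x$lambda2))
  invisible(x)
}

#' Supported model kinds
#' @keywords internal
MODEL_KINDS <- c("weight_decay_primitive", "effort_primitive", "state_space_effort")

#' Default parameters for each model kind
#'
#' The standard simulation settings: the primitive models learn with
#' eta = 0.5 and the state-space model with eta = 0.04; the per-trial
#' forgetting products are eta*lambda1 = 0.0015 (weight decay),
#' eta*lambda2 = 0.0015 (state space) and eta*lambda2 = 0.03 (effort
#' primitive). Because forgetting is specified as the product eta*lambda,
#' the stored lambdas are those products divided by eta.
#'
#' @param model_kind one of `"weight_decay_primitive"`, `"effort_primitive"`,
#'   `"state_space_effort"`.
#' @return a `learner_params` object.
#' @examples
#' default_params("effort_primitive")  # eta = 0.5, lambda2 = 0.06
#' @export
default_params <- function(model_kind) {
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  switch(model_kind,
    weight_decay_primitive = learner_params(eta = 0.5, lambda1 = 0.0015 / 0.5),
    effort_primitive       = learner_params(eta = 0.5, lambda2 = 0.03 / 0.5),
    state_space_effort     = learner_params(eta = 0.04, lambda2 = 0.0015 / 0.04))
}

#' Motor command produced by a weight vector
#'
#' The compensatory command at direction theta is the linear readout
#' \eqn{x(\theta) = \sum_i W_i A_i(\theta)} of the primitive activities.
#'
#' @param weights numeric vector of length N (the adaptable weights; command
#'   units, newtons for force fields or degrees for visuomotor rotations).
#' @param basis a `primitive_basis`.
#' @param theta direction in radians.
#' @return scalar command.
#' @export
motor_command <- function(weights, basis, theta) {
  stopifnot_basis(basis)
  if (!is.numeric(weights) || length(weights) != basis$n_primitives) {
    stop("'weights' length must equal the basis size", call. = FALSE)
  }
  sum(weights * activities(basis, theta))
}

#' One gradient-descent update of the primitive weights
#'
#' Applies the master update
#' \deqn{W_{i,t+1} = (1 - \eta\lambda_1) W_{i,t}
#'   - \tfrac{\eta}{N}\lambda_2 x_t(\theta_t) A_i(\theta_t)
#'   + \tfrac{\eta}{N} e_t A_i(\theta_t),}
#' where x_t is computed from the current weights. With lambda2 = 0 this is
#' the weight-decay rule; with lambda1 = 0 the effort-minimization rule; with
#' both zero, pure error correction. The error- and effort-gradient terms
#' carry the conventional 1/N normalization so that the command-level
#' learning gain is governed by the normalized recruitment overlap G/N and
#' is stable independent of the population size; the multiplicative
#' forgetting factor (1 - eta*lambda1) acts on each weight directly and is
#' not population-summed, so it is not rescaled.
#'
#' Updates are applied on every trial, including error-clamp trials (where
#' the caller passes `error = 0`); the decay/effort terms remaining active
#' during clamps is precisely what produces memory decay.
#'
#' @param weights current weight vector.
#' @param basis a `primitive_basis`.
#' @param theta_t the trial's target direction, radians.
#' @param error the trial's movement error e_t (0 in clamp trials).
#' @param params a `learner_params`.
#' @return the updated weight vector.
#' @export
update_weights <- function(weights, basis, theta_t, error, params) {
  stopifnot_basis(basis)
  if (!inherits(params, "learner_params")) stop("'params' must be learner_params", call. = FALSE)
  if (!is.numeric(weights) || length(weights) != basis$n_primitives) {
    stop("'weights' length must equal the basis size", call. = FALSE)
  }
  if (!is.numeric(error) || length(error) != 1L || !is.finite(error)) {
    stop("'error' must be a finite scalar", call. = FALSE)
  }
  a <- activities(basis, theta_t)
  x <- sum(weights * a)
  g <- params$eta / basis$n_primitives
  (1 - params$eta * params$lambda1) * weights +
    g * (error - params$lambda2 * x) * a
}

#' One update of the scalar state-space model
#'
#' The state-space model tracks only the scalar command x and applies
#' \deqn{x_{t+1} = (1 - \eta\lambda_2) x_t + \eta e_t} on every trial: the
#' effort term decays the memory at a rate independent of the trial's
#' direction, and error correction (eta * e) drives adaptation.
#'
#' @param command current scalar command x.
#' @param error the trial's movement error (0 in clamp trials).
#' @param params a `learner_params` (lambda1 is ignored; the model has no
#'   weights to decay).
#' @return the updated scalar command.
#' @export
update_state_space <- function(command, error, params) {
  if (!inherits(params, "learner_params")) stop("'params' must be learner_params", call. = FALSE)
  if (!is.numeric(command) || length(command) != 1L || !is.finite(command)) {
    stop("'command' must be a finite scalar", call. = FALSE)
  }
  if (!is.numeric(error) || length(error) != 1L || !is.finite(error)) {
    stop("'error' must be a finite scalar", call. = FALSE)
  }
  (1 - params$eta * params$lambda2) * command + params$eta * error
}

#' Command-space recursion (generalization-function form)
#'
#' Propagates the command profile one trial forward purely in command space,
#' without touching weights, using the normalized generalization function
#' Ghat = G/N:
#' \deqn{x_{t+1}(\theta) = (1 - \eta\lambda_1) x_t(\theta)
#'   - \eta\lambda_2 \hat G(\theta_t, \theta)\, x_t(\theta_t)
#'   + \eta e_t \hat G(\theta_t, \theta).}
#' With lambda2 = 0 the decay factor is the same for every probe direction
#' (context-independent forgetting); with lambda1 = 0 the decay is weighted
#' by the recruitment overlap Ghat(theta_t, theta) and is therefore fastest
#' at the trial's own direction (context-dependent forgetting). The
#' recursion is algebraically identical to simulating [update_weights()] and
#' reading out [motor_command()], and serves as the package's independent
#' oracle for the weight-space engine.
#'
#' @param commands_by_angle named numeric vector: current x_t(theta) at each
#'   tracked probe angle. Names are the angle values as produced by
#'   [format_angle()]; an entry for `theta_t` must be present.
#' @param basis a `primitive_basis`.
#' @param theta_t the trial's target direction, radians.
#' @param error the trial's movement error (0 in clamp trials).
#' @param params a `learner_params`.
#' @return named numeric vector of x_{t+1}(theta), same names.
#' @export
recursive_command_update <- function(commands_by_angle, basis, theta_t, error, params) {
  stopifnot_basis(basis)
  if (!inherits(params, "learner_params")) stop("'params' must be learner_params", call. = FALSE)
  key <- format_angle(theta_t)
  if (is.null(names(commands_by_angle)) || !(key %in% names(commands_by_angle))) {
    stop(sprintf("'commands_by_angle' lacks an entry for theta_t = %s", key),
         call. = FALSE)
  }
  if (!is.finite(error)) stop("'error' must be finite", call. = FALSE)
  x_t <- commands_by_angle[[key]]
  angles <- vapply(names(commands_by_angle), function(s) as.numeric(s), numeric(1))
  ghat <- vapply(angles, function(th)
    generalization_empirical(basis, theta_t, th), numeric(1)) / basis$n_primitives
  out <- (1 - params$eta * params$lambda1) * commands_by_angle +
    params$eta * (error - params$lambda2 * x_t) * ghat
  names(out) <- names(commands_by_angle)
  out
}

#' Canonical string key for a probe angle
#'
#' Full-precision representation used to key command profiles and CSV probe
#' columns by angle.
#' @param theta angle(s) in radians.
#' @return character vector.
#' @export
format_angle <- function(theta) {
  formatC(theta, format = "g", digits = 17)
}

#' Training-phase fixed point of the command at the trained direction
#'
#' Setting the per-trial increment to zero under constant training
#' (direction theta_t, perturbation p) gives the asymptote of x(theta_t):
#' for the effort models (primitive and state space) the balance
#' e = lambda2 * x yields \eqn{x^* = p / (1 + \lambda_2)}; for the
#' weight-decay model the balance \eqn{\lambda_1 x = e \hat G} yields
#' \eqn{x^* = p \hat G / (\lambda_1 + \hat G)} with
#' \eqn{\hat G = G(\theta_t, \theta_t)/N} from the sampled basis. Only the
#' single-training-direction steady state is provided.
#'
#' @param p perturbation magnitude (command units).
#' @param params a `learner_params`.
#' @param model_kind one of [MODEL_KINDS].
#' @param basis a `primitive_basis` (required for the weight-decay model,
#'   ignored otherwise).
#' @param theta_t trained direction, radians (weight-decay model only).
#' @return scalar asymptotic command.
#' @examples
#' fixed_point_command(pi / 4, default_params("effort_primitive"),
#'                     "effort_primitive")  # pi/4 / 1.06
#' @export
fixed_point_command <- function(p, params, model_kind, basis = NULL, theta_t = 0) {
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  if (!inherits(params, "learner_params")) stop("'params' must be learner_params", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p)) {
    stop("'p' must be a finite scalar", call. = FALSE)
  }
  if (model_kind %in% c("effort_primitive", "state_space_effort")) {
    return(p / (1 + params$lambda2))
  }
  stopifnot_basis(basis)
  ghat <- generalization_empirical(basis, theta_t, theta_t) / basis$n_primitives
  p * ghat / (params$lambda1 + ghat)
}
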