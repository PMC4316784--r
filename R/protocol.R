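#' Construct a trial protocol
#'
#' @param trials data.frame with columns `index` (0-based, consecutive),
#'   `phase` (training/test/retest/relearning), `cycle` (integer or NA),
#'   `theta` (radians), `p` (perturbation, command units) and `clamp`
#'   (logical).
#' @param name protocol label.
#' @return an object of class `motor_protocol` (a data.frame with a `name`
#'   attribute).
#' @keywords internal
new_protocol <- function(trials, name) {
  stopifnot(is.data.frame(trials))
  required <- c("index", "phase", "cycle", "theta", "p", "clamp")
  missing <- setdiff(required, names(trials))
  if (length(missing)) {
    stop("protocol lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(trials) == 0L) stop("protocol has no trials", call. = FALSE)
  if (!identical(trials$index, seq_len(nrow(trials)) - 1L)) {
    stop("trial indices must be consecutive from 0", call. = FALSE)
  }
  bad <- setdiff(unique(trials$phase), PHASE_LABELS)
  if (length(bad)) {
    stop("unknown phase label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(trials$theta)) || any(!is.finite(trials$p))) {
    stop("'theta' and 'p' must be finite", call. = FALSE)
  }
  structure(trials[, required], name = as.character(name),
            class = c("motor_protocol", "data.frame"))
}

PHASE_LABELS <- c("training", "test", "retest", "relearning")

#' @export
print.motor_protocol <- function(x, ...) {
  ph <- rle(x$phase)
  cat(sprintf("motor_protocol '%s': %d trials (%s)\n", attr(x, "name"), nrow(x),
              paste(sprintf("%d %s", ph$lengths, ph$values), collapse = ", ")))
  invisible(x)
}

phase_block <- function(phase, n, theta, p, clamp, cycle = NA_integer_) {
  data.frame(index = 0L, phase = phase, cycle = as.integer(cycle),
             theta = theta, p = p, clamp = clamp)[rep(1L, n), , drop = FALSE]
}

finish_protocol <- function(blocks, name) {
  trials <- do.call(rbind, blocks)
  trials$index <- seq_len(nrow(trials)) - 1L
  rownames(trials) <- NULL
  new_protocol(trials, name)
}

#' Single-test-direction error-clamp protocol
#'
#' The first simulated design: 100 training trials at theta = 0 under
#' perturbation `p`, then 100 error-clamp test trials at `theta_test`
#' (probing how the learned command generalizes to, and decays at, the
#' tested direction), then 50 error-clamp retest trials back at theta = 0
#' (probing how much memory at the trained direction survived the test
#' block). Comparing retest levels across different `theta_test` values
#' separates context-dependent from context-independent memory decay.
#'
#' @param theta_test direction of the test trials, radians.
#' @param p perturbation magnitude during training (default pi/4).
#' @return a `motor_protocol` of exactly 250 trials.
#' @export
build_simulation1 <- function(theta_test, p = pi / 4) {
  if (!is.finite(theta_test) || !is.finite(p)) stop("inputs must be finite", call. = FALSE)
  finish_protocol(list(
    phase_block("training", 100L, theta = 0, p = p, clamp = FALSE),
    phase_block("test",     100L, theta = theta_test, p = p, clamp = TRUE),
    phase_block("retest",    50L, theta = 0, p = p, clamp = TRUE)
  ), sprintf("sim1(theta_test=%.6g, p=%.6g)", theta_test, p))
}

#' Alternating test/relearning protocol over a direction grid
#'
#' The second simulated design: 200 training trials at theta = 0 under
#' perturbation `p`, followed by K cycles, each consisting of 20 error-clamp
#' test trials at a direction \eqn{\theta'_k = -\pi + 2\pi k / K} followed by
#' 100 relearning trials at theta = 0 (same perturbation, no clamp). The
#' integers k form a seeded uniform random permutation of 0..K-1, so every
#' grid direction is tested exactly once; within a cycle the test direction
#' is fixed. The test blocks measure generalization, the relearning blocks
#' measure how much memory at theta = 0 was lost while testing at theta'.
#'
#' @param K number of cycles / tested directions (>= 1; 16 in the standard
#'   design).
#' @param p perturbation magnitude (default pi/4).
#' @param seed integer seed for the direction permutation.
#' @return a `motor_protocol` of exactly 200 + 120 K trials, with the cycle
#'   index recorded on test and relearning trials.
#' @export
build_simulation2 <- function(K, p = pi / 4, seed = 1L) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K < 1 ||
      K != as.integer(K)) {
    stop("'K' must be a positive integer", call. = FALSE)
  }
  if (!is.finite(p)) stop("'p' must be finite", call. = FALSE)
  K <- as.integer(K)
  ks <- local_seed(seed, sample.int(K) - 1L)  # permutation of 0..K-1
  blocks <- list(phase_block("training", 200L, theta = 0, p = p, clamp = FALSE))
  for (c_idx in seq_len(K)) {
    theta_prime <- -pi + 2 * pi * ks[c_idx] / K
    blocks[[length(blocks) + 1L]] <-
      phase_block("test", 20L, theta = theta_prime, p = p, clamp = TRUE,
                  cycle = c_idx - 1L)
    blocks[[length(blocks) + 1L]] <-
      phase_block("relearning", 100L, theta = 0, p = p, clamp = FALSE,
                  cycle = c_idx - 1L)
  }
  finish_protocol(blocks, sprintf("sim2(K=%d, p=%.6g, seed=%d)", K, p, seed))
}

#' Load a protocol from a YAML or JSON config
#'
#' The config declares ordered phases; each phase expands to a block of
#' identical trials. Angles and perturbations may be numbers or symbolic
#' fractions of pi such as `"pi/4"` or `"-pi/12"` (see [parse_angle()]).
#'
#' Schema:
#' \preformatted{
#' name: my-design
#' phases:
#'   - {label: training, n_trials: 100, theta: 0,      p: "pi/4", clamp: false}
#'   - {label: test,     n_trials: 100, theta: "pi/6", p: "pi/4", clamp: true}
#'   - {label: retest,   n_trials: 50,  theta: 0,      p: "pi/4", clamp: true}
#' }
#' An optional `cycle` field per phase carries a 0-based cycle index.
#'
#' @param path path to a YAML or JSON file (YAML is a superset of JSON, so
#'   both parse).
#' @return a `motor_protocol`.
#' @export
load_protocol <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse protocol config '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  if (is.null(cfg$phases) || length(cfg$phases) == 0L) {
    stop("protocol config: 'phases' is missing or empty", call. = FALSE)
  }
  name <- if (is.null(cfg$name)) basename(path) else as.character(cfg$name)
  blocks <- lapply(seq_along(cfg$phases), function(i) {
    ph <- cfg$phases[[i]]
    where <- sprintf("phases[%d]", i)
    for (f in c("label", "n_trials", "theta", "clamp")) {
      if (is.null(ph[[f]])) stop(sprintf("protocol config: %s lacks field '%s'", where, f),
                                 call. = FALSE)
    }
    if (!ph$label %in% PHASE_LABELS) {
      stop(sprintf("protocol config: %s has unknown label '%s' (allowed: %s)",
                   where, ph$label, paste(PHASE_LABELS, collapse = ", ")), call. = FALSE)
    }
    n <- ph$n_trials
    if (!is.numeric(n) || n < 1 || n != as.integer(n)) {
      stop(sprintf("protocol config: %s has invalid n_trials", where), call. = FALSE)
    }
    p_val <- if (is.null(ph$p)) 0 else parse_angle(ph$p)
    cyc <- if (is.null(ph$cycle)) NA_integer_ else as.integer(ph$cycle)
    phase_block(ph$label, as.integer(n), theta = parse_angle(ph$theta),
                p = p_val, clamp = isTRUE(ph$clamp), cycle = cyc)
  })
  finish_protocol(blocks, name)
}
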