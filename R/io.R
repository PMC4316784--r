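#' Export a trace to CSV
#'
#' One row per trial with columns index, phase, cycle, theta_t, p, clamp,
#' error, x_at_theta_t, and one `probe_<angle>` column per probe-grid angle
#' (angle encoded in radians with 6 decimals). Numbers are written with full
#' double precision, so identical simulations produce byte-identical files.
#'
#' @param trace a `simulation_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  if (!inherits(trace, "simulation_trace")) stop("'trace' must be a simulation_trace", call. = FALSE)
  df <- trace$records
  if (!is.null(trace$probes)) {
    pr <- as.data.frame(trace$probes)
    names(pr) <- sprintf("probe_%.6f", trace$probe_grid)
    df <- cbind(df, pr)
  }
  write_csv_full(df, path)
}

#' Export ensemble per-trial summaries to CSV
#'
#' @param ensemble a `run_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  if (!inherits(ensemble, "run_ensemble")) stop("'ensemble' must be a run_ensemble", call. = FALSE)
  write_csv_full(ensemble$summary, path)
}

# deterministic full-precision CSV writer
write_csv_full <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, format = "g", digits = 17))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a JSON metadata sidecar for a trace or ensemble
#'
#' Records the model kind, parameters, seeds, protocol name and package
#' version so that a run can be reproduced exactly.
#'
#' @param x a `simulation_trace` or `run_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(x, path) {
  meta <- if (inherits(x, "simulation_trace")) {
    list(type = "simulation_trace", model_kind = x$model_kind,
         params = unclass(x$params), basis_seed = x$basis_seed,
         n_primitives = x$n_primitives, sigma = x$sigma,
         protocol = x$protocol_name, probe_grid = x$probe_grid)
  } else if (inherits(x, "run_ensemble")) {
    list(type = "run_ensemble", model_kind = x$model_kind,
         params = unclass(x$params), n_runs = x$n_runs, base_seed = x$base_seed,
         protocol = x$traces[[1L]]$protocol_name,
         basis_seeds = vapply(x$traces, function(tr) tr$basis_seed, integer(1)))
  } else {
    stop("'x' must be a simulation_trace or run_ensemble", call. = FALSE)
  }
  meta$package_version <- as.character(utils::packageVersion("motorprim"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
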