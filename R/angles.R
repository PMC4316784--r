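#' Wrap an angle into [-pi, pi)
#'
#' Target directions and preferred directions live on the circle; all angular
#' distances in the package are computed on the wrapped difference. The
#' boundary convention maps +pi to -pi, so the output interval is half-open.
#'
#' @param theta numeric vector of angles in radians (any finite value).
#' @return numeric vector of the same length, each element congruent to the
#'   input modulo 2*pi and lying in `[-pi, pi)`.
#' @examples
#' wrap_angle(3 * pi / 2)  # -pi/2
#' wrap_angle(pi)          # -pi
#' @export
wrap_angle <- function(theta) {
  if (!is.numeric(theta) || length(theta) == 0L || any(!is.finite(theta))) {
    stop("'theta' must be finite numeric", call. = FALSE)
  }
  ((theta + pi) %% (2 * pi)) - pi
}

#' Parse an angle written as a fraction of pi
#'
#' Accepts plain numbers as well as strings such as `"pi"`, `"-pi/12"`,
#' `"3pi/4"` or `"0.5*pi"`, parsed exactly (the multiple of `pi` is computed
#' in double precision from the literal coefficients, not via string
#' evaluation). Used by the protocol config loader and the command-line
#' script so that protocols can be written with the same symbolic angles as
#' experimental designs.
#'
#' @param x a numeric scalar or a character scalar.
#' @return numeric scalar angle in radians.
#' @examples
#' parse_angle("pi/4")
#' parse_angle("-pi/12")
#' parse_angle(0.3)
#' @export
parse_angle <- function(x) {
  if (is.numeric(x)) {
    if (length(x) != 1L || !is.finite(x)) stop("angle must be a finite scalar", call. = FALSE)
    return(as.numeric(x))
  }
  if (!is.character(x) || length(x) != 1L) {
    stop("angle must be numeric or a character scalar", call. = FALSE)
  }
  s <- gsub("[[:space:]]", "", x)
  # plain numeric string
  suppressWarnings(v <- as.numeric(s))
  if (!is.na(v)) return(v)
  m <- regmatches(s, regexec(
    "^([+-]?)([0-9]*\\.?[0-9]*)\\*?pi(?:/([0-9]*\\.?[0-9]+))?$", s))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("cannot parse angle '%s' (expected e.g. 'pi/4', '-pi/12', 0.5)", x),
         call. = FALSE)
  }
  sign <- if (m[2] == "-") -1 else 1
  num <- if (m[3] == "") 1 else as.numeric(m[3])
  den <- if (is.na(m[4]) || m[4] == "") 1 else as.numeric(m[4])
  if (den == 0) stop("zero denominator in angle", call. = FALSE)
  sign * num * pi / den
}
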