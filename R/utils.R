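#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed tables in this field
#' conventionally round half up (e.g. a brightness of 44.25 is reported as
#' 44.3). `round_half_up()` implements that convention.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(44.25, 1) # 44.3
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Half-life of a first-order process
#'
#' Converts a first-order rate constant to the corresponding half-life,
#' `ln(2) / k`, in the reciprocal of `k`'s unit. For thermal off-to-on
#' relaxation this is the half-rise time of the recovery curve.
#'
#' @param k Rate constant (> 0), typically in s^-1.
#' @return Half-life in the reciprocal unit of `k`.
#' @examples
#' halflife(log(2) / 3000) # 3000 s, i.e. 50 min
#' halflife(0.0179)        # ~38.7 s
#' @export
halflife <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0)) {
    stop_photokin("invalid_rate", "`k` must be a finite positive rate constant")
  }
  log(2) / k
}

# Classed conditions so callers can distinguish failure modes.
stop_photokin <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("photokin_", class), "photokin_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_photokin("invalid_parameter", "`%s` must be finite and numeric", name)
  }
  invisible(x)
}

# Robust noise-floor estimate from first differences of a signal.
noise_floor <- function(y) {
  stats::mad(diff(y)) / sqrt(2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
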