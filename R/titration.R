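#' Construct a pH titration series
#'
#' @param ph pH values; strictly increasing, within 3-12, length >= 6.
#' @param signal Anionic-form absorbance or fluorescence (a.u.).
#' @return A tibble of class `titration_series` with columns `ph`,
#'   `signal`.
#' @export
titration_series <- function(ph, signal) {
  if (length(ph) != length(signal)) {
    stop_photokin("invalid_titration", "ph and signal lengths differ")
  }
  if (length(ph) < 6) {
    stop_photokin("invalid_titration", "a titration needs >= 6 points")
  }
  if (any(!is.finite(ph)) || any(!is.finite(signal))) {
    stop_photokin("invalid_titration", "titration values must be finite")
  }
  if (any(diff(ph) <= 0)) {
    stop_photokin("invalid_titration", "ph must be strictly increasing")
  }
  if (min(ph) < 3 || max(ph) > 12) {
    stop_photokin("invalid_titration", "ph must lie within 3-12")
  }
  out <- tibble::tibble(ph = as.numeric(ph), signal = as.numeric(signal))
  class(out) <- c("titration_series", class(out))
  out
}

#' Fit a chromophore pKa by Henderson-Hasselbalch titration
#'
#' Least-squares fit of the single-site protonation sigmoid
#' \deqn{S(pH) = \frac{S_{max}}{1 + 10^{\,h\,(pK_a - pH)}} + S_{min}}
#' to a titration series. Only the anionic chromophore absorbs/emits at
#' the green band, so the signal rises with pH and the inflection is the
#' pKa. The Hill exponent `h` defaults to 1 (one protonatable group) and
#' may be floated with `hill = NA`.
#'
#' @param ts A [titration_series()] (or data frame with `ph`, `signal`).
#' @param hill Fixed Hill exponent, or `NA` to estimate it.
#' @return An object of class `pka_fit`: list with `pka`, `stderr`,
#'   `params`, `rss`, `n_points`, `converged` and the input series.
#'   Supports [tidy()], [glance()] and [autoplot()]. Raises an
#'   unidentifiable error when the series carries no inflection, and a
#'   partial-coverage warning when the data do not span one pH unit on
#'   each side of the fitted pKa.
#' @examples
#' ts <- gen_titration(6.3, sigma = 0, seed = 1)
#' fit_pka(ts)$pka
#' @export
fit_pka <- function(ts, hill = 1) {
  if (!inherits(ts, "titration_series")) ts <- titration_series(ts$ph, ts$signal)
  rng <- diff(range(ts$signal))
  if (rng < 10 * noise_floor(ts$signal) || rng == 0) {
    stop_photokin("unidentifiable",
                  "titration signal is flat: no protonation transition in range")
  }
  float_hill <- is.na(hill)
  # initial pKa: pH at the half-amplitude crossing
  half <- min(ts$signal) + rng / 2
  pka0 <- ts$ph[which.min(abs(ts$signal - half))]
  start <- c(pka = pka0, smax = rng, smin = min(ts$signal))
  lower <- c(min(ts$ph), 0, -Inf)
  upper <- c(max(ts$ph), Inf, Inf)
  if (float_hill) {
    start <- c(start, hill = 1)
    lower <- c(lower, 0.2); upper <- c(upper, 5)
  }
  model <- function(p, ph) {
    h <- if (float_hill) p[["hill"]] else hill
    p[["smax"]] / (1 + 10^(h * (p[["pka"]] - ph))) + p[["smin"]]
  }
  out <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper,
    fn = function(p) ts$signal - model(p, ts$ph),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  params <- stats::setNames(as.numeric(out$par), names(start))
  stderr <- tryCatch({
    cf <- summary(out)$coefficients
    stats::setNames(cf[, "Std. Error"], names(start))
  }, error = function(e) stats::setNames(rep(NA_real_, length(start)),
                                         names(start)))
  pka <- params[["pka"]]
  if (pka <= min(ts$ph) + 1e-9 || pka >= max(ts$ph) - 1e-9) {
    stop_photokin("unidentifiable",
                  "fitted pKa sits on the edge of the sampled pH range")
  }
  if (pka - min(ts$ph) < 1 || max(ts$ph) - pka < 1) {
    warning("titration covers less than 1 pH unit on one side of the pKa; ",
            "estimate may be poorly constrained", call. = FALSE)
  }
  structure(list(pka = pka, stderr = stderr[["pka"]], params = params,
                 param_stderr = stderr, rss = out$deviance,
                 n_points = nrow(ts), converged = out$info %in% 1:4,
                 hill = if (float_hill) params[["hill"]] else hill,
                 series = ts,
                 fitted = model(params, ts$ph)),
            class = "pka_fit")
}

#' @export
print.pka_fit <- function(x, ...) {
  cat(sprintf("<pka_fit: pKa = %.3f ± %.3g (Hill %.2f, %d points)>\n",
              x$pka, x$stderr, x$hill, x$n_points))
  invisible(x)
}

#' @rdname fit_pka
#' @param x A `pka_fit`.
#' @param ... Unused.
#' @method tidy pka_fit
#' @export
tidy.pka_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = as.numeric(x$params),
                 std.error = as.numeric(x$param_stderr))
}

#' @rdname fit_pka
#' @method glance pka_fit
#' @export
glance.pka_fit <- function(x, ...) {
  tibble::tibble(pka = x$pka, stderr = x$stderr, hill = x$hill,
                 rss = x$rss, n = x$n_points, converged = x$converged)
}

#' @rdname fit_pka
#' @param object A `pka_fit`.
#' @method autoplot pka_fit
#' @export
autoplot.pka_fit <- function(object, ...) {
  d <- tibble::tibble(ph = object$series$ph, signal = object$series$signal,
                      fitted = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ph)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$signal)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$pka, linetype = 2) +
    ggplot2::labs(x = "pH", y = "anionic-form signal (a.u.)",
                  title = sprintf("pKa = %.2f", object$pka))
}

#' Brightness of a fluorescent protein
#'
#' The product of the molar extinction coefficient and the fluorescence
#' quantum yield. Reported tables conventionally print brightness in
#' 1e3 M^-1 cm^-1 to one decimal, rounding half up; pass `epsilon` in the
#' same 1e3 unit to reproduce them.
#'
#' @param epsilon Molar extinction coefficient (> 0), conventionally in
#'   1e3 M^-1 cm^-1.
#' @param phi Fluorescence quantum yield, in `[0, 1]`.
#' @param digits If non-NULL, round half-up to this many decimals as in
#'   printed tables.
#' @return `epsilon * phi` (same unit as `epsilon`).
#' @examples
#' brightness(75.0, 0.59)             # 44.25
#' brightness(75.0, 0.59, digits = 1) # 44.3 as printed
#' @export
brightness <- function(epsilon, phi, digits = NULL) {
  if (!is.numeric(epsilon) || any(!is.finite(epsilon)) || any(epsilon <= 0)) {
    stop_photokin("invalid_parameter", "`epsilon` must be finite and > 0")
  }
  if (!is.numeric(phi) || any(!is.finite(phi)) || any(phi < 0 | phi > 1)) {
    stop_photokin("invalid_parameter", "`phi` must lie in [0, 1]")
  }
  b <- epsilon * phi
  if (!is.null(digits)) b <- round_half_up(b, digits)
  b
}
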