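#' Construct a time trace
#'
#' A time trace is the universal fitting input: a sampled intensity (or
#' absorbance) versus time record carried as a tibble with columns `t`
#' (seconds, strictly increasing) and `y` (arbitrary units), plus
#' illumination metadata and a `kind` label attached as attributes.
#'
#' @param t Time grid in seconds; strictly increasing, `t[1] >= 0`.
#' @param y Signal values (a.u.); same length as `t`, all finite.
#' @param kind One of `"photoconversion"`, `"switch_on_off"`, `"relaxation"`.
#' @param illumination Named list of metadata, typically `wavelength_nm`,
#'   `irradiance_mW_cm2` and `duration_s`.
#' @return A tibble of class `kin_trace` with columns `t` and `y`.
#' @examples
#' tr <- time_trace(0:59, exp(-0.05 * (0:59)), kind = "switch_on_off")
#' @export
time_trace <- function(t, y,
                       kind = c("photoconversion", "switch_on_off", "relaxation"),
                       illumination = list()) {
  kind <- match.arg(kind)
  if (length(t) != length(y)) {
    stop_photokin("invalid_trace", "`t` and `y` must have the same length")
  }
  if (length(t) < 8) {
    stop_photokin("invalid_trace", "a trace needs at least 8 samples, got %d", length(t))
  }
  if (any(!is.finite(t)) || any(!is.finite(y))) {
    stop_photokin("invalid_trace", "`t` and `y` must be finite")
  }
  if (t[1] < 0 || any(diff(t) <= 0)) {
    stop_photokin("invalid_trace", "`t` must be strictly increasing and start at >= 0")
  }
  out <- tibble::tibble(t = as.numeric(t), y = as.numeric(y))
  class(out) <- c("kin_trace", class(out))
  attr(out, "kind") <- kind
  attr(out, "illumination") <- illumination
  out
}

#' @export
print.kin_trace <- function(x, ...) {
  illum <- attr(x, "illumination")
  cat(sprintf("<kin_trace: %s, %d points, t in [%g, %g] s>\n",
              attr(x, "kind"), nrow(x), x$t[1], x$t[nrow(x)]))
  if (length(illum)) {
    cat("  illumination:", paste(names(illum), unlist(illum), sep = " = ",
                                 collapse = ", "), "\n")
  }
  NextMethod()
}

as_time_trace <- function(x, kind = "switch_on_off") {
  if (inherits(x, "kin_trace")) return(x)
  if (is.data.frame(x) && all(c("t", "y") %in% names(x))) {
    return(time_trace(x$t, x$y, kind = kind))
  }
  stop_photokin("invalid_trace", "expected a kin_trace or a data frame with columns `t` and `y`")
}

#' Plot a time trace
#'
#' @param object A `kin_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kin_trace
#' @export
autoplot.kin_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "time (s)", y = "signal (a.u.)",
                  title = attr(object, "kind"))
}
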