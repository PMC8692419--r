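#' Photoconversion model parameters
#'
#' Parameters of the green-to-red photoconversion model, a consecutive
#' first-order process Green -> Red -> Bleached observed on the red form:
#' \deqn{I_{red}(t) = I \frac{k_1}{k_2 - k_1}\left(e^{-k_1 t} - e^{-k_2 t}\right) + c}
#' The first exponential describes red-form formation under 400 nm light,
#' the second its photodestruction; `c` collects background and residual
#' signal.
#'
#' @param I Pre-exponential amplitude (a.u., >= 0).
#' @param k1 Red-form formation rate (s^-1, > 0).
#' @param k2 Red-form photodestruction rate (s^-1, >= 0).
#' @param c Background + residual signal (a.u.).
#' @return An object of class `conversion_params`.
#' @examples
#' conversion_params(1, 0.011, 0.002)
#' @export
conversion_params <- function(I, k1, k2, c = 0) {
  check_finite(c(I, k1, k2, c), "conversion parameters")
  if (k1 <= 0) stop_photokin("invalid_parameter", "`k1` must be > 0")
  if (k2 < 0) stop_photokin("invalid_parameter", "`k2` must be >= 0")
  if (I < 0) stop_photokin("invalid_parameter", "`I` must be >= 0")
  structure(list(I = I, k1 = k1, k2 = k2, c = c), class = "conversion_params")
}

#' Bi-exponential photoswitching parameters
#'
#' Parameters of the on-to-off photoswitching decay under 470 nm light:
#' \deqn{I(t) = I_1 e^{-k_1 t} \mp I_2 e^{-k_2 t} + c}
#' With `opposed = TRUE` the second component is subtracted (first-cycle
#' behaviour: the negative component reflects a concurrent rise in green
#' fluorescence at the detection wavelength); with `opposed = FALSE` both
#' components have the same sign (second and later cycles, and all
#' C175A-type variants). The sign is carried by `opposed`, never by a
#' negative amplitude.
#'
#' @param I1,I2 Component amplitudes (a.u., >= 0).
#' @param k1,k2 Component rates (s^-1, > 0).
#' @param c Baseline offset (a.u.).
#' @param opposed Logical flag selecting the sign of the second component.
#' @return An object of class `biexp_params`.
#' @examples
#' biexp_params(1, 0.0055, 0.27, 0.0098, opposed = TRUE)
#' @export
biexp_params <- function(I1, k1, I2, k2, c = 0, opposed = TRUE) {
  check_finite(c(I1, k1, I2, k2, c), "biexponential parameters")
  if (I1 < 0 || I2 < 0) stop_photokin("invalid_parameter", "amplitudes must be >= 0")
  if (k1 <= 0 || k2 <= 0) stop_photokin("invalid_parameter", "rates must be > 0")
  structure(list(I1 = I1, k1 = k1, I2 = I2, k2 = k2, c = c,
                 opposed = isTRUE(opposed)),
            class = "biexp_params")
}

#' Thermal relaxation parameters
#'
#' Parameters of the mono-exponential dark recovery of the anionic-form
#' absorbance after off-switching:
#' \deqn{A(t) = A_0 (1 - e^{-k t}) + c}
#'
#' @param A0 Recovery amplitude (a.u., >= 0).
#' @param k Recovery rate (s^-1 unless the trace declares another unit, > 0).
#' @param c Offset (a.u.).
#' @return An object of class `monoexp_params`.
#' @examples
#' monoexp_params(1, 0.0179)
#' @export
monoexp_params <- function(A0, k, c = 0) {
  check_finite(c(A0, k, c), "relaxation parameters")
  if (A0 < 0) stop_photokin("invalid_parameter", "`A0` must be >= 0")
  if (k <= 0) stop_photokin("invalid_parameter", "`k` must be > 0")
  structure(list(A0 = A0, k = k, c = c), class = "monoexp_params")
}

#' Evaluate the photoconversion model
#'
#' Pointwise evaluation of the consecutive-reaction red fluorescence curve.
#' The model is singular at `k1 == k2`; by default that raises a
#' degenerate-parameters error to surface identifiability problems, but
#' `k_equal_limit = TRUE` evaluates the analytic limit
#' \eqn{I k_1 t e^{-k_1 t} + c} instead.
#'
#' @param p A [conversion_params()] object.
#' @param t Time grid in seconds (>= 0).
#' @param k_equal_limit Evaluate the L'Hopital limit when `k1 == k2`?
#' @return Numeric intensity series, same length as `t`.
#' @examples
#' p <- conversion_params(1, 0.011, 0.002)
#' eval_photoconversion(p, c(0, 60, 600))
#' @export
eval_photoconversion <- function(p, t, k_equal_limit = FALSE) {
  stopifnot(inherits(p, "conversion_params"))
  check_finite(t, "t")
  if (any(t < 0)) stop_photokin("invalid_parameter", "`t` must be >= 0")
  if (p$k1 == p$k2) {
    if (!k_equal_limit) {
      stop_photokin("degenerate_parameters",
                    "k1 == k2: the two-exponential form is singular; set `k_equal_limit = TRUE` for the analytic limit")
    }
    return(p$I * p$k1 * t * exp(-p$k1 * t) + p$c)
  }
  p$I * p$k1 / (p$k2 - p$k1) * (exp(-p$k1 * t) - exp(-p$k2 * t)) + p$c
}

#' Evaluate the bi-exponential photoswitching model
#'
#' @param p A [biexp_params()] object.
#' @param t Time grid in seconds (>= 0).
#' @return Numeric intensity series.
#' @examples
#' p <- biexp_params(1, 0.0055, 0.27, 0.0098, opposed = TRUE)
#' eval_biexp(p, seq(0, 600, by = 60))
#' @export
eval_biexp <- function(p, t) {
  stopifnot(inherits(p, "biexp_params"))
  check_finite(t, "t")
  if (any(t < 0)) stop_photokin("invalid_parameter", "`t` must be >= 0")
  s <- if (p$opposed) -1 else 1
  p$I1 * exp(-p$k1 * t) + s * p$I2 * exp(-p$k2 * t) + p$c
}

#' Evaluate the thermal relaxation model
#'
#' @param p A [monoexp_params()] object.
#' @param t Time grid (>= 0), in the reciprocal unit of `p$k`.
#' @return Numeric absorbance series; monotone non-decreasing, `c` at `t = 0`
#'   and `A0 + c` at large `t`.
#' @examples
#' eval_relaxation(monoexp_params(1, 0.0179), c(0, halflife(0.0179)))
#' @export
eval_relaxation <- function(p, t) {
  stopifnot(inherits(p, "monoexp_params"))
  check_finite(t, "t")
  if (any(t < 0)) stop_photokin("invalid_parameter", "`t` must be >= 0")
  p$A0 * (1 - exp(-p$k * t)) + p$c
}

#' Normalization divisor for photoconversion traces
#'
#' The reporting convention normalizes red fluorescence to
#' `Imax = I * (k1 - k2) / k1`, derived from the consecutive-reaction model
#' so that 1 reflects the maximal red-form fluorescence in the absence of
#' photodestruction. Note this expression equals neither the analytic
#' maximum of the curve nor its `k2 = 0` plateau (which is `I`); the
#' plateau convention is available as `method = "plateau"`.
#'
#' @param p A [conversion_params()] object with `k1 > k2` (otherwise the
#'   reported divisor is <= 0 and normalization is undefined).
#' @param method `"reported"` (default) for `I*(k1-k2)/k1`, `"plateau"`
#'   for `I`.
#' @return The scalar divisor.
#' @export
conversion_imax <- function(p, method = c("reported", "plateau")) {
  stopifnot(inherits(p, "conversion_params"))
  method <- match.arg(method)
  imax <- switch(method,
                 reported = p$I * (p$k1 - p$k2) / p$k1,
                 plateau  = p$I)
  if (imax <= 0) {
    stop_photokin("normalization_undefined",
                  "Imax = %g <= 0 (requires k1 > k2 and I > 0); normalization undefined", imax)
  }
  imax
}

#' Normalize a photoconversion trace
#'
#' Divides a trace (or raw signal vector) by [conversion_imax()]. On a
#' noise-free model curve the normalized signal then has supremum <= 1
#' under the reported convention.
#'
#' @param trace A `kin_trace`, data frame with `t`/`y`, or numeric vector.
#' @param p A [conversion_params()] object.
#' @inheritParams conversion_imax
#' @return Same shape as `trace` with the signal divided by `Imax`.
#' @export
normalize_trace <- function(trace, p, method = c("reported", "plateau")) {
  imax <- conversion_imax(p, method)
  if (is.numeric(trace)) return(trace / imax)
  tr <- as_time_trace(trace, kind = "photoconversion")
  tr$y <- tr$y / imax
  tr
}
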