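#' Define a first-order kinetic scheme
#'
#' A generic monomolecular reaction network: named states, rate-labelled
#' transitions between them, initial populations, and an observable that is
#' linear in the state populations (fluorescence weights). This is the
#' brute-force oracle for the closed-form models and the simulator for the
#' proposed cysteine photo-oxidation mechanism.
#'
#' @param states Character vector of state labels (e.g. `c("Green", "Red",
#'   "Bleached")`).
#' @param transitions Data frame with columns `from`, `to`, `rate` (s^-1,
#'   all >= 0); states must appear in `states`.
#' @param initial Named numeric vector of nonnegative initial populations;
#'   missing states default to 0.
#' @param observable Named numeric vector of finite per-state weights
#'   mapping populations to signal; missing states default to 0.
#' @return An object of class `kinetic_scheme`.
#' @examples
#' sc <- kinetic_scheme(
#'   states = c("Green", "Red", "Bleached"),
#'   transitions = data.frame(from = c("Green", "Red"),
#'                            to = c("Red", "Bleached"),
#'                            rate = c(0.011, 0.002)),
#'   initial = c(Green = 1),
#'   observable = c(Red = 1)
#' )
#' @export
kinetic_scheme <- function(states, transitions, initial, observable) {
  states <- as.character(states)
  if (anyDuplicated(states)) stop_photokin("invalid_scheme", "duplicate state labels")
  transitions <- as.data.frame(transitions)
  if (nrow(transitions) > 0) {
    if (!all(c("from", "to", "rate") %in% names(transitions))) {
      stop_photokin("invalid_scheme", "`transitions` needs columns from, to, rate")
    }
    if (!all(transitions$from %in% states) || !all(transitions$to %in% states)) {
      stop_photokin("invalid_scheme", "transition endpoints must be declared states")
    }
    if (any(!is.finite(transitions$rate)) || any(transitions$rate < 0)) {
      stop_photokin("invalid_scheme", "all rates must be finite and >= 0")
    }
  }
  full <- function(x, what) {
    v <- stats::setNames(numeric(length(states)), states)
    if (length(x)) {
      if (is.null(names(x)) || !all(names(x) %in% states)) {
        stop_photokin("invalid_scheme", "`%s` must be named by declared states", what)
      }
      v[names(x)] <- x
    }
    v
  }
  init <- full(initial, "initial")
  if (any(init < 0)) stop_photokin("invalid_scheme", "initial populations must be >= 0")
  obs <- full(observable, "observable")
  if (any(!is.finite(obs))) stop_photokin("invalid_scheme", "observable weights must be finite")
  structure(list(states = states, transitions = transitions,
                 initial = init, observable = obs),
            class = "kinetic_scheme")
}

# Rate matrix A such that dx/dt = A x for the linear first-order system.
scheme_rate_matrix <- function(s) {
  n <- length(s$states)
  A <- matrix(0, n, n, dimnames = list(s$states, s$states))
  if (nrow(s$transitions)) {
    for (i in seq_len(nrow(s$transitions))) {
      fr <- s$transitions$from[i]; to <- s$transitions$to[i]
      k <- s$transitions$rate[i]
      A[fr, fr] <- A[fr, fr] - k
      A[to, fr] <- A[to, fr] + k
    }
  }
  A
}

#' Integrate a kinetic scheme
#'
#' Numerically integrates the linear ODE system of a [kinetic_scheme()]
#' with an adaptive stiff-capable solver (`deSolve::lsoda`, relative
#' tolerance 1e-8, absolute 1e-10). Populations stay nonnegative and, for
#' a closed scheme, total population is conserved to within integrator
#' tolerance. The observable is the weighted sum of populations.
#'
#' @param scheme A [kinetic_scheme()].
#' @param t Strictly increasing time grid starting at 0 (seconds).
#' @param rtol,atol Integrator tolerances.
#' @return A tibble with `t`, one population column per state, and
#'   `observable`.
#' @export
integrate_scheme <- function(scheme, t, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  check_finite(t, "t")
  if (t[1] != 0 || any(diff(t) <= 0)) {
    stop_photokin("invalid_parameter", "`t` must be strictly increasing from 0")
  }
  A <- scheme_rate_matrix(scheme)
  deriv <- function(time, y, parms) list(as.vector(A %*% y))
  sol <- deSolve::lsoda(y = scheme$initial, times = t, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  pops <- as.data.frame(sol)[, c("time", scheme$states), drop = FALSE]
  # clip tiny negative excursions from the integrator
  pops[scheme$states] <- lapply(pops[scheme$states], function(x) pmax(x, 0))
  out <- tibble::as_tibble(pops)
  names(out)[1] <- "t"
  out$observable <- as.vector(as.matrix(out[scheme$states]) %*% scheme$observable)
  out
}

#' Consecutive photoconversion scheme
#'
#' Convenience constructor for the Green -> Red -> Bleached scheme that
#' underlies the photoconversion closed form: red fluorescence is the
#' observable, all population starts green.
#'
#' @param k1 Green-to-red formation rate (s^-1).
#' @param k2 Red photodestruction rate (s^-1).
#' @return A [kinetic_scheme()].
#' @export
photoconversion_scheme <- function(k1, k2) {
  kinetic_scheme(
    states = c("Green", "Red", "Bleached"),
    transitions = data.frame(from = c("Green", "Red"),
                             to = c("Red", "Bleached"),
                             rate = c(k1, k2)),
    initial = c(Green = 1),
    observable = c(Red = 1)
  )
}

#' Two-population photo-oxidation switching scheme
#'
#' Reconstruction of the proposed mechanism distinguishing C175-bearing
#' variants: under 470 nm light the native on state both switches off
#' (`k_sw`) and, during the first cycle only, photo-oxidizes at cysteine
#' 175 (`k_ox`) into a second population whose on state switches off with
#' its own rate (`k_sw_ox`). The 400 nm regeneration pulse between cycles
#' is treated as instantaneous and complete (Off -> On, OxOff -> OxOn).
#' This is a stated modelling assumption, not a printed mechanism.
#'
#' @param k_sw On-to-off switching rate of the native population (s^-1).
#' @param k_ox First-cycle photo-oxidation rate On -> OxOn (s^-1).
#' @param k_sw_ox On-to-off switching rate of the oxidized population (s^-1).
#' @param oxidation Include the oxidation channel (first cycle) or not
#'   (later cycles, where the populations are fixed).
#' @param initial Named initial populations over
#'   `c("On", "Off", "OxOn", "OxOff")`; defaults to all native on.
#' @param observable Fluorescence weights; both on states emit by default.
#' @return A [kinetic_scheme()].
#' @export
photooxidation_scheme <- function(k_sw, k_ox, k_sw_ox,
                                  oxidation = TRUE,
                                  initial = c(On = 1),
                                  observable = c(On = 1, OxOn = 1)) {
  tr <- data.frame(from = c("On", "OxOn"), to = c("Off", "OxOff"),
                   rate = c(k_sw, k_sw_ox))
  if (oxidation) {
    tr <- rbind(tr, data.frame(from = "On", to = "OxOn", rate = k_ox))
  }
  kinetic_scheme(states = c("On", "Off", "OxOn", "OxOff"),
                 transitions = tr, initial = initial, observable = observable)
}

#' Simulate repeated switching cycles of the photo-oxidation scheme
#'
#' Integrates the two-population scheme across `n_cycles` periods of
#' 470 nm illumination, applying complete 400 nm regeneration (off states
#' returned to the corresponding on states) between cycles. Oxidation is
#' active only during the first cycle.
#'
#' @inheritParams photooxidation_scheme
#' @param n_cycles Number of illumination cycles.
#' @param t Time grid within each cycle (strictly increasing from 0, s).
#' @return A tibble with columns `cycle`, `t`, the four populations and
#'   `observable`.
#' @export
simulate_photooxidation_cycles <- function(k_sw, k_ox, k_sw_ox, n_cycles,
                                           t = seq(0, 600, by = 1)) {
  pops <- c(On = 1, Off = 0, OxOn = 0, OxOff = 0)
  out <- vector("list", n_cycles)
  for (cyc in seq_len(n_cycles)) {
    sc <- photooxidation_scheme(k_sw, k_ox, k_sw_ox,
                                oxidation = (cyc == 1), initial = pops)
    sol <- integrate_scheme(sc, t)
    out[[cyc]] <- dplyr::mutate(sol, cycle = cyc, .before = 1)
    last <- sol[nrow(sol), ]
    # complete regeneration: 400 nm pulse maps off states back to on
    pops <- c(On = last$On + last$Off, Off = 0,
              OxOn = last$OxOn + last$OxOff, OxOff = 0)
  }
  dplyr::bind_rows(out)
}
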