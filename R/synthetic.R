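# Seeded generators emulating the illumination experiments: 400 nm
# photoconversion traces, repeated 470 nm on-to-off switching cycles with
# instantaneous 400 nm regeneration, thermal recovery, Gaussian emission
# bands and Henderson-Hasselbalch titrations. Noise is additive Gaussian
# (default sigma 0.01 of the unit peak amplitude); identical seeds give
# identical output.

with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

default_grid <- function(n_points, t_end) {
  if (n_points < 8) stop_photokin("invalid_parameter", "`n_points` must be >= 8")
  seq(0, t_end, length.out = n_points)
}

#' Generate a photoconversion trace
#'
#' Simulates the red-fluorescence kinetics recorded during 400 nm
#' (146 mW/cm^2) illumination: the preset's consecutive-reaction curve
#' plus additive Gaussian noise. Defaults match the experimental window
#' (10 min at 1 Hz).
#'
#' @param preset A [variant_preset()] (or variant name).
#' @param n_points Number of samples (>= 8).
#' @param t_end End of the illumination window (s).
#' @param sigma Gaussian noise standard deviation (a.u.).
#' @param seed Integer seed; identical seeds give identical traces.
#' @return A `kin_trace` of kind `"photoconversion"`.
#' @examples
#' tr <- gen_conversion_trace(variant_preset("mSAASoti"), sigma = 0, seed = 1)
#' @export
gen_conversion_trace <- function(preset, n_points = 601, t_end = 600,
                                 sigma = 0.01, seed = NULL) {
  preset <- as_preset(preset)
  t <- default_grid(n_points, t_end)
  y <- eval_photoconversion(preset$conversion, t)
  y <- y + with_opt_seed(seed, stats::rnorm(length(t), 0, sigma))
  time_trace(t, y, kind = "photoconversion",
             illumination = list(wavelength_nm = 400, irradiance_mW_cm2 = 146,
                                 duration_s = t_end))
}

#' Generate a thermal relaxation trace
#'
#' Simulates the dark recovery of the anionic-form absorbance after
#' off-switching: mono-exponential rise plus Gaussian noise.
#'
#' @inheritParams gen_conversion_trace
#' @return A `kin_trace` of kind `"relaxation"`.
#' @export
gen_relaxation_trace <- function(preset, n_points = 601, t_end = 600,
                                 sigma = 0.01, seed = NULL) {
  preset <- as_preset(preset)
  t <- default_grid(n_points, t_end)
  y <- eval_relaxation(preset$relaxation, t)
  y <- y + with_opt_seed(seed, stats::rnorm(length(t), 0, sigma))
  time_trace(t, y, kind = "relaxation", illumination = list(dark = TRUE))
}

#' Generate a photoswitching cycle series
#'
#' Simulates repeated on-to-off switching under 470 nm light
#' (167 mW/cm^2, 10 min per cycle) separated by complete 400 nm
#' regeneration pulses (10 s, 21.3 mW/cm^2), in pH 9.2 carbonate buffer.
#' Cycle 1 follows the preset's first-cycle kinetics (opposed second
#' component for wild-type-like variants, same sign or absent for
#' C175A-type); later cycles follow the second-cycle kinetics. Amplitudes
#' are anchored so the pre-illumination intensity of cycle `n` is
#' `fatigue^(n-1)` times that of cycle 1. For wild-type-like presets a
#' per-cycle emission spectrum is attached whose band centre shifts by
#' `blue_shift_per_cycle` nm each cycle.
#'
#' @inheritParams gen_conversion_trace
#' @param n_cycles Number of cycles (>= 1).
#' @param spectra Attach per-cycle emission spectra?
#' @return A [cycle_series()].
#' @examples
#' cs <- gen_cycle_series(variant_preset("mSAASoti"), n_cycles = 2,
#'                        sigma = 0, seed = 1)
#' @export
gen_cycle_series <- function(preset, n_cycles = 3, n_points = 601,
                             t_end = 600, sigma = 0.01, seed = NULL,
                             spectra = TRUE) {
  preset <- as_preset(preset)
  if (n_cycles < 1) stop_photokin("invalid_parameter", "`n_cycles` must be >= 1")
  t <- default_grid(n_points, t_end)
  p1 <- preset$switch_cycle1
  p2 <- preset$switch_cycle2
  y0_1 <- eval_biexp(p1, 0)            # cycle-1 pre-illumination intensity
  y0_2 <- eval_biexp(p2, 0)
  with_opt_seed(seed, {
    cycles <- vector("list", n_cycles)
    specs <- if (spectra) vector("list", n_cycles) else NULL
    for (cyc in seq_len(n_cycles)) {
      if (cyc == 1) {
        p <- p1
      } else {
        scale <- preset$fatigue^(cyc - 1) * y0_1 / y0_2
        p <- biexp_params(p2$I1 * scale, p2$k1, p2$I2 * scale, p2$k2,
                          c = p2$c * scale, opposed = FALSE)
      }
      y <- eval_biexp(p, t) + stats::rnorm(length(t), 0, sigma)
      cycles[[cyc]] <- time_trace(
        t, y, kind = "switch_on_off",
        illumination = list(wavelength_nm = 470, irradiance_mW_cm2 = 167,
                            duration_s = t_end, cycle = cyc))
      if (spectra) {
        centre <- 519 + preset$blue_shift_per_cycle * (cyc - 1)
        wl <- seq(480, 650, by = 1)
        amp <- preset$fatigue^(cyc - 1)
        inten <- amp * exp(-(wl - centre)^2 / (2 * 15^2)) +
          stats::rnorm(length(wl), 0, sigma)
        specs[[cyc]] <- emission_spectrum(wl, inten)
      }
    }
    cycle_series(cycles, buffer_ph = 9.2,
                 regeneration = list(wavelength_nm = 400, duration_s = 10,
                                     irradiance_mW_cm2 = 21.3),
                 spectra = specs)
  })
}

#' Generate a pH titration series
#'
#' Henderson-Hasselbalch sigmoid of the anionic-form signal plus Gaussian
#' noise.
#'
#' @param pka True chromophore pKa.
#' @param n_points Number of pH points (>= 6).
#' @param ph_range Range of the pH grid; must span `pka`.
#' @param s_max,s_min Sigmoid amplitude and floor (a.u.).
#' @inheritParams gen_conversion_trace
#' @return A [titration_series()].
#' @examples
#' ts <- gen_titration(6.3, sigma = 0, seed = 1)
#' @export
gen_titration <- function(pka, n_points = 15, ph_range = c(4, 9),
                          s_max = 1, s_min = 0, sigma = 0.01, seed = NULL) {
  if (n_points < 6) stop_photokin("invalid_parameter", "`n_points` must be >= 6")
  if (pka <= ph_range[1] || pka >= ph_range[2]) {
    stop_photokin("invalid_parameter", "`ph_range` must span `pka`")
  }
  ph <- seq(ph_range[1], ph_range[2], length.out = n_points)
  sig <- s_max / (1 + 10^(pka - ph)) + s_min
  sig <- sig + with_opt_seed(seed, stats::rnorm(length(ph), 0, sigma))
  titration_series(ph, sig)
}

#' Generate a before/after emission spectrum pair
#'
#' Two Gaussian emission bands on a 1 nm grid over 480-650 nm: the second
#' band centre is displaced by `shift` nm (negative = blue-shift), as
#' observed after 470 nm illumination of wild-type-like variants.
#'
#' @param center Band centre of the "before" spectrum (nm).
#' @param shift Centre displacement of the "after" spectrum (nm).
#' @param width Gaussian standard deviation (nm, > 0).
#' @inheritParams gen_conversion_trace
#' @return A list with elements `before` and `after`, both
#'   [emission_spectrum()] objects.
#' @examples
#' pair <- gen_spectrum_pair(shift = -3, sigma = 0, seed = 1)
#' @export
gen_spectrum_pair <- function(center = 519, shift = -3, width = 15,
                              sigma = 0.01, seed = NULL) {
  if (width <= 0) stop_photokin("invalid_parameter", "`width` must be > 0")
  wl <- seq(480, 650, by = 1)
  with_opt_seed(seed, {
    before <- exp(-(wl - center)^2 / (2 * width^2)) +
      stats::rnorm(length(wl), 0, sigma)
    after <- exp(-(wl - (center + shift))^2 / (2 * width^2)) +
      stats::rnorm(length(wl), 0, sigma)
    list(before = emission_spectrum(wl, before),
         after = emission_spectrum(wl, after))
  })
}

as_preset <- function(x) {
  if (inherits(x, "variant_preset")) return(x)
  if (is.character(x) && length(x) == 1) return(variant_preset(x))
  stop_photokin("unknown_preset", "expected a variant_preset or a variant name")
}
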