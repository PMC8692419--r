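#' Variant preset table
#'
#' Kinetic and photophysical parameters of the SAASoti cysteine-mutant
#' panel, transcribed from the published characterization (rate constants
#' of the switching, recovery and photoconversion kinetics; chromophore
#' pKa; molar extinction; quantum yield) plus generator-only fields.
#' Fatigue factors and per-cycle blue-shift magnitudes are reconstructed
#' illustrative defaults, not measured values; the `reconstructed` column
#' flags them.
#'
#' @return A tibble, one row per variant, with rates in 1e-3 s^-1 as in
#'   the standard table convention.
#' @examples
#' variant_presets()
#' @export
variant_presets <- function() {
  path <- system.file("extdata", "variant_presets.csv", package = "photokin")
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    name = "c", sw1_opposed = "l", reconstructed = "c",
                    .default = "d"))
}

#' Fetch one variant preset
#'
#' Expands a row of [variant_presets()] into typed parameter objects
#' usable with the model evaluators and generators. Rates are converted
#' from the tabulated 1e-3 s^-1 to s^-1; amplitudes are unit-normalized
#' (`I = I1 = A0 = 1`, zero baseline). Mono-exponential cycles (no second
#' switching component) are represented with `I2 = 0`.
#'
#' @param name Variant name, e.g. `"mSAASoti"`, `"C105V"`, `"C175A"`,
#'   `"C21N_C71G_C175A"`.
#' @return A list of class `variant_preset` with elements `name`, `pka`,
#'   `epsilon` (1e3 M^-1 cm^-1), `phi`, `conversion`
#'   ([conversion_params()]), `switch_cycle1` and `switch_cycle2`
#'   ([biexp_params()]), `relaxation` ([monoexp_params()]), `fatigue`,
#'   `blue_shift_per_cycle` (nm) and `c175a_like` (no opposed first-cycle
#'   component).
#' @examples
#' variant_preset("mSAASoti")$conversion
#' @export
variant_preset <- function(name) {
  tab <- variant_presets()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1) {
    stop_photokin("unknown_preset", "unknown variant `%s`; see variant_presets()$name", name)
  }
  as_biexp <- function(ratio, k1_e3, k2_e3, opposed) {
    k1 <- k1_e3 / 1e3
    if (is.na(k2_e3) || ratio == 0) {
      biexp_params(1, k1, 0, 3 * k1, c = 0, opposed = opposed)
    } else {
      biexp_params(1, k1, ratio, k2_e3 / 1e3, c = 0, opposed = opposed)
    }
  }
  structure(list(
    name = row$name,
    pka = row$pka,
    epsilon = row$epsilon_1e3,
    phi = row$phi,
    conversion = conversion_params(1, row$conv_k1_1e3 / 1e3,
                                   row$conv_k2_1e3 / 1e3, c = 0),
    switch_cycle1 = as_biexp(row$sw1_ratio, row$sw1_k1_1e3, row$sw1_k2_1e3,
                             row$sw1_opposed),
    switch_cycle2 = as_biexp(row$sw2_ratio, row$sw2_k1_1e3, row$sw2_k2_1e3,
                             FALSE),
    relaxation = monoexp_params(1, row$relax_k_1e3 / 1e3, c = 0),
    fatigue = row$fatigue,
    blue_shift_per_cycle = row$blue_shift_per_cycle_nm,
    c175a_like = !row$sw1_opposed
  ), class = "variant_preset")
}

#' @export
print.variant_preset <- function(x, ...) {
  cat(sprintf("<variant_preset: %s%s>\n", x$name,
              if (x$c175a_like) " (C175A-type)" else ""))
  cat(sprintf("  pKa %.1f, epsilon %.1f x10^3 M^-1 cm^-1, phi %.2f\n",
              x$pka, x$epsilon, x$phi))
  cat(sprintf("  conversion k1 = %g, k2 = %g s^-1; recovery k = %g s^-1\n",
              x$conversion$k1, x$conversion$k2, x$relaxation$k))
  invisible(x)
}
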