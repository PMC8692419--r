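test_that("identical seeds give identical output from every generator", {
  p <- variant_preset("mSAASoti")
  expect_identical(gen_conversion_trace(p, seed = 42)$y,
                   gen_conversion_trace(p, seed = 42)$y)
  expect_identical(gen_relaxation_trace(p, seed = 42)$y,
                   gen_relaxation_trace(p, seed = 42)$y)
  a <- gen_cycle_series(p, n_cycles = 2, seed = 42)
  b <- gen_cycle_series(p, n_cycles = 2, seed = 42)
  expect_identical(lapply(a$cycles, `[[`, "y"), lapply(b$cycles, `[[`, "y"))
  expect_identical(gen_titration(6.3, seed = 42)$signal,
                   gen_titration(6.3, seed = 42)$signal)
  pa <- gen_spectrum_pair(seed = 42); pb <- gen_spectrum_pair(seed = 42)
  expect_identical(pa$before$intensity, pb$before$intensity)
  # and different seeds differ
  expect_false(identical(gen_conversion_trace(p, seed = 1)$y,
                         gen_conversion_trace(p, seed = 2)$y))
})

test_that("zero-noise generators reproduce the closed forms exactly", {
  p <- variant_preset("mSAASoti")
  tr <- gen_conversion_trace(p, sigma = 0, seed = 1)
  expect_identical(tr$y, eval_photoconversion(p$conversion, tr$t))
  rl <- gen_relaxation_trace(p, sigma = 0, seed = 1)
  expect_identical(rl$y, eval_relaxation(p$relaxation, rl$t))
  cs <- gen_cycle_series(p, n_cycles = 1, sigma = 0, seed = 1, spectra = FALSE)
  expect_identical(cs$cycles[[1]]$y, eval_biexp(p$switch_cycle1, cs$cycles[[1]]$t))
  ts <- gen_titration(6.3, sigma = 0, ph_range = c(4, 9), n_points = 11)
  expect_identical(ts$signal, 1 / (1 + 10^(6.3 - ts$ph)))
})

test_that("generated conversion traces fit back to the preset constants", {
  tr <- gen_conversion_trace("mSAASoti", sigma = 0.01, seed = 3)
  fit <- fit_trace(tr, "photoconversion")
  expect_equal(coef(fit)[["k1"]], 0.011, tolerance = 0.05)
  expect_equal(coef(fit)[["k2"]], 0.002, tolerance = 0.05)
  expect_equal(attr(tr, "illumination")$wavelength_nm, 400)
  expect_equal(attr(tr, "illumination")$irradiance_mW_cm2, 146)
})

test_that("cycle series carry protocol metadata and per-cycle structure", {
  cs1 <- gen_cycle_series("mSAASoti", n_cycles = 1, sigma = 0.01, seed = 1)
  expect_length(cs1, 1)
  cs <- gen_cycle_series("mSAASoti", n_cycles = 3, sigma = 0, seed = 1)
  expect_equal(cs$buffer_ph, 9.2)
  expect_equal(cs$regeneration$wavelength_nm, 400)
  expect_equal(cs$regeneration$duration_s, 10)
  # cycle-2/cycle-1 initial rates follow the preset constants
  k1_1 <- variant_preset("mSAASoti")$switch_cycle1$k1
  k1_2 <- variant_preset("mSAASoti")$switch_cycle2$k1
  expect_equal(k1_2 / k1_1, 7.8 / 5.5, tolerance = 1e-9)
  # wild-type emission spectra blue-shift cycle by cycle
  m1 <- emission_max(cs$spectra[[1]])
  m3 <- emission_max(cs$spectra[[3]])
  expect_equal(m3 - m1, 2 * variant_preset("mSAASoti")$blue_shift_per_cycle,
               tolerance = 0.1)
})

test_that("C175A-type series are same-sign with geometric fatigue", {
  cs <- gen_cycle_series("C175A", n_cycles = 3, sigma = 0, seed = 1)
  # no initial rise anywhere: all cycles decay monotonically
  for (tr in cs$cycles) expect_true(all(diff(tr$y) <= 1e-12))
  y0 <- sapply(cs$cycles, function(tr) tr$y[1])
  expect_equal(y0 / y0[1], 0.85^(0:2), tolerance = 1e-9)
  # spectra do not shift for C175A-type presets
  expect_equal(emission_max(cs$spectra[[1]]), emission_max(cs$spectra[[3]]),
               tolerance = 0.05)
})

test_that("the preset table transcribes all variants with valid parameters", {
  tab <- variant_presets()
  expect_equal(nrow(tab), 9)
  expect_setequal(
    tab$name,
    c("mSAASoti", "C21N", "C105V", "C71V", "C117S", "C21N_C71V",
      "C175A", "C21N_C175A", "C21N_C71G_C175A"))
  for (nm in tab$name) {
    p <- variant_preset(nm)
    expect_s3_class(p$conversion, "conversion_params")
    expect_s3_class(p$switch_cycle1, "biexp_params")
    expect_s3_class(p$relaxation, "monoexp_params")
    expect_true(p$fatigue > 0 && p$fatigue <= 1)
  }
  # C175A-containing variants lack the opposed first-cycle component
  expect_true(all(!tab$sw1_opposed == grepl("C175A", tab$name)))
  # reconstructed fields are flagged
  expect_true(all(grepl("fatigue", tab$reconstructed)))
  expect_error(variant_preset("nope"), class = "photokin_unknown_preset")
})

test_that("generator preconditions are enforced", {
  expect_error(gen_conversion_trace("mSAASoti", n_points = 4),
               class = "photokin_invalid_parameter")
  expect_error(gen_titration(6.3, ph_range = c(7, 9)),
               class = "photokin_invalid_parameter")
  expect_error(gen_spectrum_pair(width = 0), class = "photokin_invalid_parameter")
  expect_error(gen_cycle_series("mSAASoti", n_cycles = 0),
               class = "photokin_invalid_parameter")
})
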