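test_that("photoconversion curve has the consecutive-reaction shape", {
  p <- conversion_params(1, 0.011, 0.002)
  # both exponentials cancel at t = 0
  expect_equal(eval_photoconversion(p, 0), 0)
  # both exponentials vanish at long times, leaving the background
  p_c <- conversion_params(1, 0.011, 0.002, c = 0.3)
  expect_equal(eval_photoconversion(p_c, 1e7), 0.3, tolerance = 1e-9)
  # curve stays above background for positive rates and amplitude
  y <- eval_photoconversion(p_c, grid600)
  expect_true(all(y >= 0.3 - 1e-12))
  # single interior maximum at t_max = log(k1/k2)/(k1 - k2)
  tmax <- log(0.011 / 0.002) / (0.011 - 0.002)
  expect_equal(grid600[which.max(eval_photoconversion(p, grid600))], round(tmax))
})

test_that("photoconversion limit mode handles k1 == k2, default errors", {
  p <- conversion_params(1, 0.01, 0.01)
  expect_error(eval_photoconversion(p, 0:10), class = "photokin_degenerate_parameters")
  y <- eval_photoconversion(p, c(0, 50, 100), k_equal_limit = TRUE)
  expect_equal(y, 1 * 0.01 * c(0, 50, 100) * exp(-0.01 * c(0, 50, 100)))
})

test_that("photoconversion plateau approaches I + c as destruction vanishes", {
  p <- conversion_params(2, 0.011, 1e-9, c = 0.1)
  expect_equal(eval_photoconversion(p, 1e5), 2.1, tolerance = 1e-3)
})

test_that("parameter constructors validate their invariants", {
  expect_error(conversion_params(1, -0.01, 0.002), class = "photokin_invalid_parameter")
  expect_error(conversion_params(1, 0.01, -1), class = "photokin_invalid_parameter")
  expect_error(conversion_params(NaN, 0.01, 0.002), class = "photokin_invalid_parameter")
  expect_error(biexp_params(-1, 0.01, 0.2, 0.02), class = "photokin_invalid_parameter")
  expect_error(biexp_params(1, 0, 0.2, 0.02), class = "photokin_invalid_parameter")
  expect_error(monoexp_params(1, 0), class = "photokin_invalid_parameter")
  expect_error(eval_photoconversion(conversion_params(1, 0.01, 0.002), -1),
               class = "photokin_invalid_parameter")
})

test_that("bi-exponential switching model follows its sign convention", {
  # I2 = 0 reduces to a single exponential: value 1 at t = 0
  p0 <- biexp_params(1, 0.0055, 0, 0.0098, opposed = TRUE)
  expect_equal(eval_biexp(p0, 0), 1)
  # equal amplitudes and rates cancel exactly in the opposed form
  pc <- biexp_params(0.5, 0.01, 0.5, 0.01, c = 0.2, opposed = TRUE)
  expect_equal(eval_biexp(pc, c(0, 10, 300)), rep(0.2, 3))
  # mSAASoti first-cycle constants: I2*k2 < I1*k1, so the opposed curve
  # is monotonically decreasing from t = 0
  p <- biexp_params(1, 0.0055, 0.27, 0.0098, opposed = TRUE)
  expect_true(all(diff(eval_biexp(p, grid600)) < 0))
  # opposed flag flips only the sign of the second component
  ps <- biexp_params(1, 0.0055, 0.27, 0.0098, opposed = FALSE)
  t <- c(0, 30, 200)
  expect_equal(eval_biexp(ps, t) - eval_biexp(p, t),
               2 * 0.27 * exp(-0.0098 * t))
})

test_that("same-sign bi-exponential decay is non-increasing", {
  withr::with_seed(42, {
    for (i in 1:25) {
      p <- biexp_params(runif(1, 0, 2), 10^runif(1, -4, -1),
                        runif(1, 0, 2), 10^runif(1, -4, -1),
                        c = runif(1, 0, 0.5), opposed = FALSE)
      expect_true(all(diff(eval_biexp(p, grid600)) <= 0))
    }
  })
})

test_that("thermal relaxation rises monotonically from c to A0 + c", {
  p <- monoexp_params(1, 0.0179)
  expect_equal(eval_relaxation(p, 0), 0)
  expect_equal(eval_relaxation(p, 1e6), 1, tolerance = 1e-9)
  expect_true(all(diff(eval_relaxation(p, grid600)) > 0))
  # half-rise time equals halflife(k) exactly when c = 0
  expect_equal(eval_relaxation(p, halflife(0.0179)), 0.5)
})

test_that("halflife converts rate constants to half-lives", {
  expect_equal(halflife(log(2) / 3000), 3000)     # 50 min
  expect_equal(halflife(log(2)), 1)
  expect_equal(halflife(0.0179), log(2) / 0.0179) # ~38.7 s
  expect_equal(halflife(0.0179), 38.7, tolerance = 1e-3)
  expect_error(halflife(0), class = "photokin_invalid_rate")
  expect_error(halflife(-1), class = "photokin_invalid_rate")
})

test_that("normalization divisor follows the reported Imax convention", {
  p <- conversion_params(1, 0.011, 0.002)
  expect_equal(conversion_imax(p), 1 * (0.011 - 0.002) / 0.011) # 9/11
  # reduces to I when there is no photodestruction
  expect_equal(conversion_imax(conversion_params(2, 0.011, 0)), 2)
  # plateau alternative is I itself
  expect_equal(conversion_imax(p, method = "plateau"), 1)
  # k1 <= k2 makes the reported divisor non-positive
  expect_error(conversion_imax(conversion_params(1, 0.002, 0.011)),
               class = "photokin_normalization_undefined")
})

test_that("normalized noise-free curves have supremum at most 1", {
  p <- conversion_params(1.7, 0.011, 0.002)
  tr <- noise_free_trace(p, "photoconversion")
  norm <- normalize_trace(tr, p)
  expect_lte(max(norm$y), 1)
  # an all-zero trace normalizes to all zeros
  expect_equal(normalize_trace(rep(0, 10), p), rep(0, 10))
})

test_that("time_trace validates its invariants", {
  expect_error(time_trace(1:5, 1:5), class = "photokin_invalid_trace")
  expect_error(time_trace(c(0, 2, 1, 3:8), rep(1, 9)), class = "photokin_invalid_trace")
  expect_error(time_trace(0:8, c(rep(1, 8), NA)), class = "photokin_invalid_trace")
  expect_error(time_trace(-1:7, rep(1, 9)), class = "photokin_invalid_trace")
  tr <- time_trace(0:9, rnorm(10), kind = "relaxation",
                   illumination = list(wavelength_nm = 400))
  expect_s3_class(tr, "kin_trace")
  expect_equal(attr(tr, "kind"), "relaxation")
})
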