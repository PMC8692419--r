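test_that("init_guess returns usable starting values", {
  # relaxation: log-linear slope on the half-rise lands within 20%
  tr <- noise_free_trace(monoexp_params(1, 0.0179), "relaxation")
  g <- init_guess(tr, "relaxation")
  expect_lt(rel_err(g[["k"]], 0.0179), 0.2)
  # photoconversion: formation guess faster than destruction guess
  tr1 <- noise_free_trace(conversion_params(1, 0.011, 0.002), "photoconversion")
  g1 <- init_guess(tr1, "photoconversion")
  expect_gt(g1[["k1"]], g1[["k2"]])
  # a flat trace is uninformative
  flat <- time_trace(0:99, rep(1, 100) + rnorm(100, 0, 1e-4), "relaxation")
  expect_error(init_guess(flat, "relaxation"),
               class = "photokin_uninformative_trace")
})

test_that("noise-free traces round-trip through fit_trace to 1e-5", {
  cases <- list(
    list(id = "photoconversion", p = conversion_params(1, 0.011, 0.002),
         truth = c(I = 1, k1 = 0.011, k2 = 0.002)),
    list(id = "photoconversion", p = conversion_params(0.8, 0.046, 0.009),
         truth = c(I = 0.8, k1 = 0.046, k2 = 0.009)),
    list(id = "biexp_opposed", p = biexp_params(1, 0.0055, 0.27, 0.0098, opposed = TRUE),
         truth = c(I1 = 1, k1 = 0.0055, I2 = 0.27, k2 = 0.0098)),
    list(id = "biexp", p = biexp_params(1, 0.0078, 0.26, 0.0247, opposed = FALSE),
         truth = c(I1 = 1, k1 = 0.0078, I2 = 0.26, k2 = 0.0247)),
    list(id = "monoexp", p = biexp_params(1, 0.0035, 0, 0.01, opposed = FALSE),
         truth = c(I1 = 1, k1 = 0.0035)),
    list(id = "relaxation", p = monoexp_params(1, 0.0179),
         truth = c(A0 = 1, k = 0.0179))
  )
  for (cs in cases) {
    kind <- if (cs$id == "relaxation") "relaxation" else "switch_on_off"
    fit <- fit_trace(noise_free_trace(cs$p, kind), cs$id)
    expect_true(fit$converged)
    expect_lt(max(rel_err(coef(fit)[names(cs$truth)], cs$truth)), 1e-5,
              label = paste(cs$id, "parameter recovery"))
    expect_lt(fit$rss, 1e-10)
  }
})

test_that("random noise-free parameter draws round-trip for every model", {
  withr::with_seed(99, {
    for (i in 1:12) {
      k_slow <- 10^runif(1, -3.2, -2)
      k_fast <- k_slow * runif(1, 2.5, 6)
      amp <- runif(1, 0.5, 2)
      cases <- list(
        list(id = "photoconversion",
             p = conversion_params(amp, k_fast, k_slow),
             truth = c(k1 = k_fast, k2 = k_slow)),
        list(id = "biexp",
             p = biexp_params(amp, k_slow, amp * runif(1, 0.15, 0.8), k_fast,
                              opposed = FALSE),
             truth = c(k1 = k_slow, k2 = k_fast)),
        list(id = "relaxation", p = monoexp_params(amp, k_slow),
             truth = c(k = k_slow))
      )
      for (cs in cases) {
        kind <- if (cs$id == "relaxation") "relaxation" else "switch_on_off"
        fit <- fit_trace(noise_free_trace(cs$p, kind), cs$id)
        expect_lt(max(rel_err(coef(fit)[names(cs$truth)], cs$truth)), 1e-5,
                  label = sprintf("%s draw %d", cs$id, i))
      }
    }
  })
})

test_that("photoconversion fits report the k1 >= k2 labelling convention", {
  # the consecutive-reaction curve is invariant under swapping its rates
  # with an amplitude rescale, so the label is fixed by convention
  fit <- fit_trace(noise_free_trace(conversion_params(1, 0.011, 0.002),
                                    "photoconversion"), "photoconversion")
  expect_gte(coef(fit)[["k1"]], coef(fit)[["k2"]])
  # same-sign bi-exponential fits are ordered k1 <= k2 as in kinetics tables
  fit2 <- fit_trace(noise_free_trace(
    biexp_params(1, 0.0247, 0.26, 0.0078, opposed = FALSE), "switch_on_off"),
    "biexp")
  expect_lte(coef(fit2)[["k1"]], coef(fit2)[["k2"]])
})

test_that("noisy traces recover the generating rate to 2% in the median", {
  p <- monoexp_params(1, 0.0179)
  khat <- sapply(1:40, function(sd) {
    y <- withr::with_seed(sd, eval_relaxation(p, grid600) + rnorm(601, 0, 0.01))
    coef(fit_trace(time_trace(grid600, y, "relaxation"), "relaxation"))[["k"]]
  })
  expect_lt(rel_err(median(khat), 0.0179), 0.02)
})

test_that("reported standard errors are calibrated against Monte-Carlo spread", {
  p <- monoexp_params(1, 0.0179)
  out <- sapply(1:200, function(sd) {
    y <- withr::with_seed(sd, eval_relaxation(p, grid600) + rnorm(601, 0, 0.01))
    f <- fit_trace(time_trace(grid600, y, "relaxation"), "relaxation")
    c(k = coef(f)[["k"]], se = f$stderr[["k"]])
  })
  mc_sd <- sd(out["k", ])
  med_se <- median(out["se", ])
  expect_gt(med_se / mc_sd, 0.5)
  expect_lt(med_se / mc_sd, 2)
})

test_that("fixing the baseline removes it from the fit", {
  p <- biexp_params(1, 0.0055, 0.27, 0.0098, opposed = TRUE)
  y <- withr::with_seed(5, eval_biexp(p, grid600) + rnorm(601, 0, 0.01))
  f <- fit_trace(time_trace(grid600, y, "switch_on_off"), "biexp_opposed",
                 fix = c(c = 0))
  expect_identical(coef(f)[["c"]], 0)
  expect_true(is.na(f$stderr[["c"]]))
  expect_error(fit_trace(time_trace(grid600, y, "switch_on_off"),
                         "biexp_opposed", fix = c(zz = 1)),
               class = "photokin_invalid_parameter")
})

test_that("model selection ranks candidates by AICc and flags ties", {
  # data from a pure mono-exponential: the bi-exponential's two extra
  # parameters are penalized
  pm <- biexp_params(1, 0.0055, 0, 0.01, opposed = FALSE)
  y <- withr::with_seed(7, eval_biexp(pm, grid600) + rnorm(601, 0, 0.01))
  sel <- select_model(time_trace(grid600, y, "switch_on_off"),
                      c("biexp", "monoexp"))
  expect_equal(sel$model_id[1], "monoexp")
  expect_equal(sel$rank, 1:2)
  expect_equal(sel$delta_aicc[1], 0)
  # opposed bi-exponential data at low noise: the richer model wins
  p2 <- biexp_params(1, 0.0055, 0.27, 0.0098, opposed = TRUE)
  y2 <- withr::with_seed(8, eval_biexp(p2, grid600) + rnorm(601, 0, 0.005))
  sel2 <- select_model(time_trace(grid600, y2, "switch_on_off"),
                       c("biexp_opposed", "monoexp"))
  expect_equal(sel2$model_id[1], "biexp_opposed")
  # a single candidate is returned as rank 1
  sel3 <- select_model(time_trace(grid600, y, "switch_on_off"), "monoexp")
  expect_equal(nrow(sel3), 1)
  expect_equal(sel3$rank, 1)
})

test_that("amplitude_ratio divides the bi-exponential amplitudes", {
  p <- biexp_params(2, 0.0055, 1, 0.0098, opposed = FALSE)
  f <- fit_trace(noise_free_trace(p, "switch_on_off"), "biexp")
  expect_equal(amplitude_ratio(f), 0.5, tolerance = 1e-5)
  # undefined for single-exponential models
  fr <- fit_trace(noise_free_trace(monoexp_params(1, 0.0179), "relaxation"),
                  "relaxation")
  expect_error(amplitude_ratio(fr), class = "photokin_invalid_parameter")
})

test_that("broom-style accessors expose the fit", {
  f <- fit_trace(noise_free_trace(monoexp_params(1, 0.0179), "relaxation"),
                 "relaxation")
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term, c("A0", "k", "c"))
  gl <- glance(f)
  expect_true(gl$converged)
  expect_equal(gl$n, 601)
  au <- augment(f)
  expect_named(au, c("t", "y", ".fitted", ".resid"))
  expect_equal(au$.resid, au$y - au$.fitted)
  expect_s3_class(autoplot(f), "ggplot")
})
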