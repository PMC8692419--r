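# Shared fixtures, built in code: a 1 Hz grid over the 10 min
# illumination window and noise-free model traces.

grid600 <- seq(0, 600, by = 1)

noise_free_trace <- function(params, kind, t = grid600) {
  y <- switch(class(params)[1],
              conversion_params = eval_photoconversion(params, t),
              biexp_params = eval_biexp(params, t),
              monoexp_params = eval_relaxation(params, t))
  time_trace(t, y, kind = kind)
}

# relative error, guarding against division by ~0
rel_err <- function(est, truth) abs(est - truth) / abs(truth)
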