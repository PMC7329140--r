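# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

fx_grid <- function() fx_get("grid", function() channel_grid())

# A small corpus used across decoder/analysis tests: 1 talker x 4 digits x 2.
fx_corpus_small <- function() fx_get("corpus_small", function()
  generate_corpus(1, 4, 2, seed = 11))

# Cochleagrams of the small corpus.
fx_specs_small <- function() fx_get("specs_small", function()
  lapply(fx_corpus_small()$utterances, function(u)
    cochleagram(u$waveform, u$sample_rate, fx_grid())))

# A calibrated scaled network on the small ensemble.
fx_net_scaled <- function() fx_get("net_scaled", function()
  calibrate_network(scaling_rule(alpha_tau = 1.9), fx_specs_small(),
                    fx_grid(), seed = 5))

# A synthetic Gabor-fit bank: one fitted receptive field per channel.
fx_bank_fits <- function() fx_get("bank_fits", function() {
  g <- fx_grid()
  lags <- seq(0, 40, by = 0.5)
  x_oct <- (0:52) * g$spacing
  lapply(1:53, function(m) {
    center <- (m - 1) * g$spacing
    p <- c(1, 10, 4, 30, 0, 0, center, 0.4, 0.8, 0.3,
           -0.4, 16, 5, 20, 1, 0, center, 0.5, 0.6, 1.5)
    structure(list(params = p, variance_explained = 1,
                   fitted = gabor_strf(p, lags, x_oct),
                   lag_ms = lags, x_oct = x_oct, converged = TRUE),
              class = "hsnn_gabor_fit")
  })
})

# Random binary response fixtures for the decoder.
random_binned <- function(n, m, p = 0.3) {
  structure(list(R = matrix(rbinom(n * m, 1, p), n, m), delta_t = 5,
                 duration = m * 5 / 1000),
            class = "hsnn_binned")
}

# Deterministic, perfectly separable per-class response templates.
separable_binned <- function(label, n = 6, m = 8) {
  R <- matrix(0L, n, m)
  R[(label %% n) + 1, ] <- 1L
  structure(list(R = R, delta_t = 5, duration = m * 5 / 1000),
            class = "hsnn_binned")
}
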