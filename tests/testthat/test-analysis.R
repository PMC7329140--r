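# A reference LNP simulation used by the STRF tests: drive a planted-kernel
# neuron with a DMR envelope and draw Bernoulli spikes at the frame rate.
lnp_spikes <- function(dmr, K, rate, seed) {
  env <- sweep(dmr$envelope, 2, colMeans(dmr$envelope))
  Tn <- nrow(env); L <- nrow(K)
  nfft <- stats::nextn(Tn + L, 2)
  EF <- stats::mvfft(rbind(env, matrix(0, nfft - Tn, ncol(env))))
  KF <- stats::mvfft(rbind(K, matrix(0, nfft - L, ncol(K))))
  drive <- rowSums(Re(stats::mvfft(EF * KF, inverse = TRUE)))[1:Tn] / nfft
  lam <- pmax(drive, 0)
  lam <- lam / mean(lam) * rate
  withr::with_seed(seed,
    (which(rbinom(Tn, 1, pmin(lam / dmr$frame_rate, 1)) > 0) - 0.5) /
      dmr$frame_rate)
}

planted_kernel <- function() {
  g <- fx_grid()
  lags <- seq(0, 50, by = 0.5)
  x_oct <- (0:52) * g$spacing
  K <- gabor_strf(c(1, 12, 4, 40, 0.3, 0, 2.6, 0.5, 0.8, 0.5,
                    0, 0, 1, 0, 0, 0, 0, 1, 0, 0), lags, x_oct)
  list(K = K, lags = lags, x_oct = x_oct)
}

test_that("reverse correlation recovers a planted kernel from DMR responses", {
  g <- fx_grid()
  pk <- planted_kernel()
  # polarity-balanced pair of deterministic-scan DMR probes (2 x 15 s here;
  # the acceptance suite runs the full 60 s protocol)
  d1 <- generate_dmr(15, g, wander = "sweep", phase0 = 0, audio = FALSE)
  d2 <- generate_dmr(15, g, wander = "sweep", phase0 = pi, audio = FALSE)
  s1 <- lnp_spikes(d1, pk$K, 60, seed = 101)
  s2 <- lnp_spikes(d2, pk$K, 60, seed = 102)
  strf <- combine_strf(list(estimate_strf(d1, s1), estimate_strf(d2, s2)))
  expect_gt(cor(as.vector(strf$kernel), as.vector(pk$K)), 0.85)
  expect_gt(strf$n_spikes, 100)
  # stimulus-independent spikes produce no structure above the noise floor
  null_spikes <- withr::with_seed(7, sort(runif(800, 0, 15)))
  null_strf <- estimate_strf(d1, null_spikes)
  expect_lt(max(abs(null_strf$kernel)), 6 * null_strf$noise_floor)
  # under the null, |z| > 3 should be about as rare as chance predicts
  z_frac <- mean(abs(null_strf$kernel) > 3 * null_strf$noise_floor)
  expect_lt(z_frac, 0.02)
  expect_error(estimate_strf(d1, numeric(0)), "zero spikes")
})

test_that("the STA is linear in the stored envelope", {
  g <- fx_grid()
  d <- generate_dmr(5, g, audio = FALSE, seed = 3)
  spk <- withr::with_seed(8, sort(runif(300, 0, 5)))
  a <- estimate_strf(d, spk)
  d2 <- d
  d2$envelope <- 3 * d$envelope
  b <- estimate_strf(d2, spk)
  expect_equal(b$kernel, 3 * a$kernel, tolerance = 1e-12)
})

test_that("longer probes reduce the STA noise floor as 1/sqrt(duration)", {
  g <- fx_grid()
  d1 <- generate_dmr(10, g, audio = FALSE, seed = 5)
  d2 <- generate_dmr(40, g, audio = FALSE, seed = 5)
  rate_spk <- function(d, seed) withr::with_seed(seed,
    sort(runif(round(20 * nrow(d$envelope) / d$frame_rate), 0,
               nrow(d$envelope) / d$frame_rate)))
  s1 <- estimate_strf(d1, rate_spk(d1, 1))
  s2 <- estimate_strf(d2, rate_spk(d2, 2))
  expect_equal(s1$noise_floor / s2$noise_floor, 2, tolerance = 0.2)
})

test_that("STRF metrics recover constructed latency, width and bandwidth", {
  g <- fx_grid()
  lags <- seq(0, 50, by = 0.5)
  x_oct <- (0:52) * g$spacing
  # Gaussian bump: latency 5 ms, temporal SD 2 ms -> integration time 4 ms;
  # spectral Gaussian with half-max full width 0.5 oct
  sx <- 0.5 / (2 * sqrt(2 * log(2)))
  K <- exp(-(lags - 5)^2 / (2 * 2^2)) %o% exp(-(x_oct - 2.6)^2 / (2 * sx^2))
  strf <- structure(list(kernel = K, lag_ms = lags, grid = g,
                         n_spikes = 1000L, noise_floor = 1e-6),
                    class = "hsnn_strf")
  m <- strf_metrics(strf)
  expect_equal(m$latency, 5, tolerance = 0.5)
  expect_equal(m$integration_time, 4, tolerance = 0.2)
  expect_equal(m$bandwidth, 0.5, tolerance = 0.05)
  # time-shift equivariance: +3 ms moves latency only
  K3 <- rbind(matrix(0, 6, 53), K[1:(length(lags) - 6), ])
  strf3 <- strf
  strf3$kernel <- K3
  m3 <- strf_metrics(strf3)
  expect_equal(m3$latency - m$latency, 3, tolerance = 0.5)
  expect_equal(m3$bandwidth, m$bandwidth, tolerance = 1e-6)
})

test_that("the Gabor model self-fits and tolerates noise", {
  pk <- planted_kernel()
  self <- fit_gabor(pk$K, lag_ms = pk$lags, x_oct = pk$x_oct, seed = 2)
  expect_gte(self$variance_explained, 0.999)
  noisy <- pk$K + withr::with_seed(9,
    matrix(rnorm(length(pk$K), sd = 0.1 * sd(pk$K)), nrow(pk$K)))
  nf <- fit_gabor(noisy, lag_ms = pk$lags, x_oct = pk$x_oct, seed = 2)
  expect_gte(nf$variance_explained, 0.85)
  expect_length(nf$params, 20)
})

test_that("direct-method information matches a brute-force plug-in oracle", {
  set.seed(41)
  Tn <- 100
  n_tr <- 2000
  p_t <- 0.05 + 0.4 * (sin(2 * pi * (1:Tn) / 25) + 1) / 2
  R <- matrix(rbinom(n_tr * Tn, 1, rep(p_t, each = n_tr)), n_tr, Tn)
  est <- mutual_information(R, dt_ms = 2, word_lengths = 2, fractions = 1)
  H2 <- function(p) ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))
  pairs <- cbind(p_t[1:(Tn - 1)], p_t[2:Tn])
  probs <- function(p1, p2) c((1 - p1) * (1 - p2), p1 * (1 - p2),
                              (1 - p1) * p2, p1 * p2)
  ptot <- rowMeans(apply(pairs, 1, function(pp) probs(pp[1], pp[2])))
  mi_true <- (-sum(ptot * log2(ptot)) -
                mean(apply(pairs, 1, function(pp) H2(pp[1]) + H2(pp[2])))) /
    (2 * 0.002)
  expect_equal(est$bits_per_s, mi_true, tolerance = 0.05 * mi_true)
})

test_that("information limits: deterministic and stimulus-independent rasters", {
  # identical rasters across trials: zero noise entropy
  set.seed(42)
  Rd <- matrix(rep(rbinom(300, 1, 0.3), each = 40), 40, 300)
  d <- mutual_information(Rd, word_lengths = 3, fractions = 1)
  expect_equal(d$noise_entropy_rate, 0)
  expect_equal(d$bits_per_s, d$total_entropy_rate)
  # trial-shuffled stimulus-independent rasters: MI within the bias bound
  Rn <- matrix(rbinom(50 * 500, 1, 0.2), 50, 500)
  nn <- mutual_information(Rn)
  expect_lt(abs(nn$bits_per_spike), 0.1)
  expect_true(all(nn$word_table$h_total >= 0))
})

test_that("response spectra isolate a planted sinusoid at its frequency", {
  fs <- 500
  Tn <- 8192
  n_tr <- 30
  A <- 5
  sig <- 3
  tt <- (1:Tn) / fs
  S <- 20 + A * sin(2 * pi * 10 * tt)
  set.seed(43)
  X <- matrix(rep(S, each = n_tr), n_tr, Tn) +
    matrix(rnorm(n_tr * Tn, sd = sig), n_tr)
  sp <- response_spectra(X, fs)
  # peak of the SNR curve away from DC sits at 10 Hz
  off_dc <- sp$freq > 2
  expect_equal(sp$freq[off_dc][which.max(sp$snr_db[off_dc])], 10,
               tolerance = 0.3)
  # analytic peak SNR: line power smeared over the window ENBW + signal
  # residual, against the one-sided white-noise density (n-1)/n * 2 sig^2/fs
  analytic_pk <- 10 * log10(((A^2 / 2) / sp$enbw_hz + 2 * sig^2 / (n_tr * fs)) /
                              (2 * sig^2 / fs * (1 - 1 / n_tr)))
  measured_pk <- max(sp$snr_db[off_dc])
  expect_equal(measured_pk, analytic_pk, tolerance = 1)
  # noise-free trials: noise spectrum underflows, SNR capped at the ceiling
  Xc <- matrix(rep(S, each = 4), 4, Tn)
  spc <- response_spectra(Xc, fs)
  expect_true(all(spc$snr_db <= 40))
  expect_equal(max(spc$P_nn), 0)
  expect_error(response_spectra(X[1, , drop = FALSE], fs), "2 trials")
})

test_that("band metrics integrate correctly and split additively", {
  fake <- structure(list(freq = seq(0, 250, by = 0.5),
                         P_ss = rep(1, 501), P_nn = rep(0.5, 501),
                         snr_db = rep(3, 501), n_trials = 10, enbw_hz = 1),
                    class = "hsnn_response_spectra")
  bm <- band_metrics(fake, bands = list(fluct = c(1, 25)))
  expect_equal(bm$snr_db_hz, 3 * 24) # constant integrand
  expect_equal(bm$snr_db_mean, 3)
  split <- band_metrics(fake, bands = list(a = c(1, 10), b = c(10, 25)))
  expect_equal(sum(split$snr_db_hz), bm$snr_db_hz)
  # P_ss entirely at DC: zero band modulation index
  dc_only <- fake
  dc_only$P_ss <- c(100, rep(0, 500))
  expect_equal(band_metrics(dc_only, bands = list(f = c(1, 25)))$modulation_index, 0)
  expect_error(band_metrics(fake, bands = list(bad = c(200, 400))), "outside")
})

test_that("band signal power never exceeds the total response power", {
  fs <- 500
  set.seed(44)
  X <- matrix(rnorm(20 * 4096, mean = 10), 20, 4096)
  sp <- response_spectra(X, fs)
  total_power <- trapz(sp$freq, sp$P_ss)
  bands <- band_metrics(sp, bands = list(a = c(1, 100), b = c(100, 240)))
  expect_lte(sum(bands$modulation_index) *
               (sp$P_ss[1] + sp$P_nn[1]), total_power + 1e-9)
})
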