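test_that("scaling expansion follows the power law with fixed E/I ratios", {
  r <- scaling_rule(alpha_tau = 1.9, gamma_sigma = 1.2, lambda_N = 0.8)
  p <- expand_scaling(r)
  expect_equal(nrow(p), 6)
  expect_equal(p$tau, 0.4 * 1.9^(0:5))
  expect_equal(p$tau[6], 0.4 * 1.9^5, tolerance = 1e-12) # 9.904 ms
  expect_equal(p$sigma, 0.0269 * 1.2^(0:5))
  expect_equal(p$N, 0.5 * 0.8^(0:5))
  expect_equal(p$tau_I / p$tau, rep(1.5, 6))
  expect_equal(p$sigma_I / p$sigma, rep(1.5, 6))
  expect_equal(p$beta, rep(2 / 3, 6))
  expect_equal(tau_fold_increase(r), 1.9^5) # 24.8-fold
  # identity scaling: all layers share the first-layer parameters
  pid <- expand_scaling(scaling_rule())
  expect_equal(var(pid$tau), 0)
  expect_equal(var(pid$sigma), 0)
  expect_error(scaling_rule(alpha_tau = -1), "> 0")
})

test_that("Gaussian connectivity peaks on the diagonal and is symmetric", {
  g <- fx_grid()
  conn <- build_connectivity(g, 0.0269)
  expect_equal(diag(conn$E), rep(1 / sqrt(2 * pi * 0.0269^2), 53))
  expect_equal(conn$E, t(conn$E))
  expect_equal(conn$I, t(conn$I))
  expect_true(all(conn$E >= 0) && all(conn$I >= 0))
  # inhibitory width is 1.5x excitatory: check the implied SD on a row
  mid <- 27
  wts_E <- conn$E[, mid]
  wts_I <- conn$I[, mid]
  sd_of <- function(w) sqrt(sum(w * (g$positions - g$positions[mid])^2) / sum(w))
  expect_equal(sd_of(wts_I) / sd_of(wts_E), 1.5, tolerance = 0.02)
  # truncation at 4 SD
  far <- abs(g$positions - g$positions[mid]) > 4 * 0.0269
  expect_true(all(wts_E[far] == 0))
  expect_error(build_connectivity(g, -0.1), "> 0")
})

test_that("alpha kernels peak at their time constant with unit height", {
  tau <- 2
  dt <- 0.1
  h <- psp_kernel(tau, dt)
  t_axis <- seq(0, 8 * tau, by = dt)
  expect_equal(t_axis[which.max(h)], tau)
  expect_equal(max(h), 1, tolerance = 1e-12)
  # discrete samples match the closed form pointwise
  expect_equal(h, (t_axis / tau) * exp(1 - t_axis / tau))
  # inhibitory kernel (1.5 tau) peaks at 1.5 tau
  hi <- psp_kernel(1.5 * tau, dt)
  ti <- seq(0, 8 * 1.5 * tau, by = dt)
  expect_equal(ti[which.max(hi)], 1.5 * tau)
  expect_error(psp_kernel(1, 0.5), "dt")
})

test_that("desired voltage is a linear superposition of PSP kernels", {
  g <- channel_grid(n_channels = 5, f_lo = 500, f_hi = 4000, spacing = 0.25)
  conn <- build_connectivity(g, 0.25)
  tau <- 1
  dt <- 0.1
  n <- 400
  # single presynaptic spike, beta = 0: output equals w_E * shifted EPSP
  spk <- list(numeric(0), c(10), numeric(0), numeric(0), numeric(0))
  v <- desired_voltage(spk, conn, tau, dt, beta = 0, n_steps = n)
  t_axis <- (seq_len(n) - 1) * dt
  u <- pmax(t_axis - 10, 0)
  expected <- conn$E[2, 2] * (u / tau) * exp(1 - u / tau)
  expected[u > 8 * tau] <- 0 # kernels carry an 8-tau support
  expect_equal(v[, 2], expected, tolerance = 1e-10)
  # linearity: doubling the drive doubles the voltage; sums superpose
  spk2 <- list(numeric(0), c(10, 10), numeric(0), numeric(0), numeric(0))
  v2 <- desired_voltage(spk2, conn, tau, dt, beta = 0, n_steps = n)
  expect_equal(v2, 2 * v, tolerance = 1e-12)
  # matched E/I kernels with beta = 2/3 reduce the net response
  vb <- desired_voltage(spk, conn, tau, dt, beta = 2 / 3, n_steps = n)
  expect_lt(max(vb[, 2]), max(v[, 2]))
  # zero input gives zero voltage
  v0 <- desired_voltage(lapply(1:5, function(i) numeric(0)), conn, tau, dt,
                        n_steps = n)
  expect_true(all(v0 == 0))
})

test_that("current derivation inverts the membrane filter exactly", {
  set.seed(21)
  for (rep in 1:5) {
    tau <- runif(1, 0.4, 10)
    dt <- tau / 10
    v <- cumsum(rnorm(500)) # arbitrary smooth-ish trace
    i <- derive_current(v, tau, dt, noise_snr_db = Inf)
    back <- membrane_filter(i, tau, dt)
    expect_lt(max(abs(back - v)) / max(abs(v)), 1e-9)
  }
  # with noise: subtracting the stored component restores the identity
  v <- cumsum(rnorm(2000))
  i <- derive_current(v, 2, 0.2, noise_snr_db = 15, seed = 1)
  clean <- as.numeric(i) - attr(i, "noise")
  expect_lt(max(abs(membrane_filter(clean, 2, 0.2) - v)) / max(abs(v)), 1e-9)
  # determinism given the seed
  i2 <- derive_current(v, 2, 0.2, noise_snr_db = 15, seed = 1)
  expect_identical(as.numeric(i), as.numeric(i2))
})

test_that("injected current noise realizes the 15 dB target SNR", {
  set.seed(22)
  v <- as.numeric(stats::filter(rnorm(2e5), rep(1 / 8, 8), sides = 1))
  v[is.na(v)] <- 0
  i <- derive_current(v, 1, 0.1, noise_snr_db = 15, seed = 3)
  z <- attr(i, "noise")
  sig <- as.numeric(i) - z
  expect_equal(10 * log10(mean(sig^2) / mean(z^2)), 15, tolerance = 0.5)
})

test_that("LIF interspike intervals match the closed-form oracle", {
  refrac <- 1
  theta <- 20
  set.seed(23)
  for (k in 1:20) {
    tau <- runif(1, 0.5, 10)
    current <- runif(1, theta * 1.05, theta * 6)
    dt <- 1 / ceiling(40 / tau) # <= tau/40 and divides the 1 ms refractory
    n <- round(50 * tau / dt)
    ras <- lif_simulate(rep(current, n), tau, dt, v_thresh = theta,
                        refrac_ms = refrac)
    st <- ras$spikes[[1]] * 1000 # ms
    expect_gt(length(st), 3)
    isi <- diff(st)
    oracle <- tau * log(current / (current - theta)) + refrac
    expect_true(all(abs(isi - oracle) <= dt + 1e-9))
    expect_true(all(isi >= refrac - 1e-9)) # refractory contract
  }
  # subthreshold constant current never spikes
  quiet <- lif_simulate(rep(19.9, 5000), 1, 0.05)
  expect_length(quiet$spikes[[1]], 0)
})

test_that("LIF agrees with a fine-step brute-force integration", {
  set.seed(24)
  tau <- 2
  dt <- 0.1
  n <- 3000
  current <- 25 + 15 * sin(2 * pi * (1:n) * dt / 50) + rnorm(n, sd = 4)
  ras <- lif_simulate(current, tau, dt)
  # brute force at dt/16 with sample-held current
  fine <- 16
  dtf <- dt / fine
  af <- exp(-dtf / tau)
  v <- 0; hold <- 0; spikes <- numeric(0)
  refrac_steps <- round(1 / dtf)
  for (t in seq_len(n * fine)) {
    it <- current[ceiling(t / fine)]
    if (hold > 0) { hold <- hold - 1; v <- 0 } else {
      v <- af * v + (1 - af) * it
      if (v >= 20) { spikes <- c(spikes, t * dtf); v <- 0; hold <- refrac_steps }
    }
  }
  coarse <- ras$spikes[[1]] * 1000
  expect_equal(length(coarse), length(spikes), tolerance = 1)
  m <- min(length(coarse), length(spikes))
  # each reset can add up to one coarse-grid rounding, so the k-th spike is
  # bounded by k coarse steps; the first crossing within a single step
  expect_lte(abs(coarse[1] - spikes[1]), dt + 1e-9)
  expect_true(all(abs(coarse[1:m] - spikes[1:m]) <= (1:m) * dt + 1e-9))
})

test_that("threshold calibration hits the population SD target", {
  net <- fx_net_scaled()
  specs <- fx_specs_small()
  p <- net$layers
  # reconstruct the layer-1 desired voltage and check the calibrated SD
  conn <- build_connectivity(net$grid, p$sigma[1], p$sigma_I[1])
  vs <- lapply(specs, function(s)
    desired_voltage(s$values, conn, p$tau[1], p$dt[1], drive_dt = 0.5))
  sigma_v <- sd(unlist(vs)) * net$gains[1]
  expect_equal(sigma_v, 20 / p$N[1], tolerance = 1e-6) # N = 0.5 -> 40 mV
  # doubling N halves the target SD and strictly reduces firing
  net_hi <- calibrate_network(scaling_rule(N1 = 1.0), specs[1:2],
                              fx_grid(), seed = 5)
  net_lo <- calibrate_network(scaling_rule(N1 = 0.5), specs[1:2],
                              fx_grid(), seed = 5)
  expect_equal(net_hi$gains[1] / net_lo$gains[1], 0.5, tolerance = 1e-6)
  r_hi <- mean_rate(run_network(net_hi, specs[[1]], seed = 9)[[1]])
  r_lo <- mean_rate(run_network(net_lo, specs[[1]], seed = 9)[[1]])
  expect_lt(r_hi, r_lo)
})

test_that("network runs are deterministic and silence stays silent", {
  net <- fx_net_scaled()
  sp <- fx_specs_small()[[1]]
  a <- run_network(net, sp, seed = 31)
  b <- run_network(net, sp, seed = 31)
  for (l in 1:6) expect_identical(a[[l]]$spikes, b[[l]]$spikes)
  # silence: noise power scales with the signal, so no drive -> no spikes
  silent <- sp
  silent$values[] <- 0
  out <- run_network(net, silent, seed = 32)
  rates <- vapply(out, mean_rate, 1)
  expect_true(all(rates < 1))
})

test_that("tonotopy is preserved: narrowband input stays on-channel", {
  specs <- fx_specs_small()
  net_id <- fx_get("net_identity_small", function()
    calibrate_network(scaling_rule(), specs, fx_grid(), seed = 5))
  g <- fx_grid()
  sr <- 16000
  k <- 30
  tt <- seq(0, 0.4, by = 1 / sr)
  tone <- 0.4 * sin(2 * pi * g$center_frequencies[k] * tt)
  sp <- cochleagram(tone, sr, g)
  out <- run_network(net_id, sp, seed = 33)
  counts <- lengths(out[[6]]$spikes)
  com <- sum(seq_len(53) * counts) / sum(counts)
  expect_lt(abs(com - k), 3)
})
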