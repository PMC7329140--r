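#' Estimate a spectro-temporal receptive field by reverse correlation
#'
#' Spike-triggered average of the (zero-mean) ripple envelope over lags
#' [0, max_lag], normalized by the spike count. The dynamic moving ripple is
#' statistically unbiased, so the STA converges on the neuron's linear
#' kernel.
#'
#' @param dmr an `hsnn_dmr` (its `envelope` is the stimulus design).
#' @param spikes an `hsnn_spike_raster` with a single neuron, or a numeric
#'   vector of spike times in seconds.
#' @param max_lag_ms maximum lag in ms (default 50).
#' @return an `hsnn_strf`: `kernel` (lag x channel), `lag_ms`, `grid`,
#'   `n_spikes`, `noise_floor` (analytic SD of a stimulus-independent STA).
#' @export
estimate_strf <- function(dmr, spikes, max_lag_ms = 50) {
  stopifnot(inherits(dmr, "hsnn_dmr"))
  if (inherits(spikes, "hsnn_spike_raster")) {
    if (spikes$n_neurons != 1)
      stop("pass a single neuron's spike times")
    spikes <- spikes$spikes[[1]]
  }
  if (!length(spikes)) stop("zero spikes: STRF undefined")
  env <- sweep(dmr$envelope, 2, colMeans(dmr$envelope))
  Tn <- nrow(env)
  w <- tabulate(pmin(Tn, floor(spikes * dmr$frame_rate) + 1L), nbins = Tn)
  n_lag <- round(max_lag_ms / 1000 * dmr$frame_rate)
  kernel <- cpp_sta(env, as.numeric(w), n_lag) / sum(w)
  noise_floor <- stats::sd(env) * sqrt(sum(w^2)) / sum(w)
  structure(list(kernel = kernel,
                 lag_ms = (0:n_lag) / dmr$frame_rate * 1000,
                 grid = dmr$grid, n_spikes = sum(w),
                 noise_floor = noise_floor),
            class = "hsnn_strf")
}

#' Combine STRF estimates across probe segments
#'
#' Spike-count-weighted average of spike-triggered averages measured on
#' several probe stimuli — e.g. a polarity-balanced DMR pair (phases 0 and
#' pi), which cancels even-order rectification distortions.
#'
#' @param strfs list of `hsnn_strf` with identical shapes.
#' @return an `hsnn_strf` with the pooled kernel and spike count.
#' @export
combine_strf <- function(strfs) {
  stopifnot(length(strfs) >= 1, all(vapply(strfs, inherits, TRUE, "hsnn_strf")))
  n <- vapply(strfs, `[[`, 1, "n_spikes")
  kernel <- Reduce(`+`, Map(function(s, w) s$kernel * w, strfs, n)) / sum(n)
  out <- strfs[[1]]
  out$kernel <- kernel
  out$n_spikes <- sum(n)
  out$noise_floor <- sqrt(sum((n * vapply(strfs, `[[`, 1, "noise_floor"))^2)) /
    sum(n)
  out
}

#' @export
print.hsnn_strf <- function(x, ...) {
  cat(sprintf("<hsnn_strf> %d lags x %d channels (%d spikes)\n",
              nrow(x$kernel), ncol(x$kernel), x$n_spikes))
  invisible(x)
}

#' Temporal and spectral STRF metrics
#'
#' Latency is the lag of the peak of the temporal marginal envelope (RMS
#' across frequency); integration time is twice the SD of that envelope
#' about its centroid; bandwidth is the full width at half maximum of the
#' spectral marginal envelope, in octaves.
#'
#' @param strf an `hsnn_strf`.
#' @param significance require peak |kernel| > `significance` x noise floor;
#'   metrics are NA (flagged) below it. Use 0 to disable.
#' @return list `integration_time` (ms), `latency` (ms), `bandwidth` (oct),
#'   `significant` (logical).
#' @export
strf_metrics <- function(strf, significance = 3) {
  stopifnot(inherits(strf, "hsnn_strf"))
  k <- strf$kernel
  signif_ok <- is.null(strf$noise_floor) || significance == 0 ||
    max(abs(k)) > significance * strf$noise_floor
  if (!signif_ok)
    return(list(integration_time = NA_real_, latency = NA_real_,
                bandwidth = NA_real_, significant = FALSE))
  tm <- sqrt(rowMeans(k^2)) # temporal marginal envelope
  sm <- sqrt(colMeans(k^2)) # spectral marginal envelope
  lag <- strf$lag_ms
  latency <- lag[which.max(tm)]
  centroid <- sum(lag * tm) / sum(tm)
  integration <- 2 * sqrt(sum(tm * (lag - centroid)^2) / sum(tm))
  # spectral FWHM in octaves with linear interpolation at the half crossings
  x_oct <- (seq_along(sm) - 1) * strf$grid$spacing
  half <- max(sm) / 2
  above <- which(sm >= half)
  lo <- min(above); hi <- max(above)
  interp_edge <- function(i0, i1) {
    if (i0 < 1 || i1 > length(sm) || i0 == i1) return(x_oct[max(1, min(i0, length(sm)))])
    approx(sm[c(i0, i1)], x_oct[c(i0, i1)], xout = half)$y
  }
  left <- if (lo > 1) interp_edge(lo - 1, lo) else x_oct[1]
  right <- if (hi < length(sm)) interp_edge(hi + 1, hi) else x_oct[length(sm)]
  list(integration_time = integration, latency = latency,
       bandwidth = abs(right - left), significant = TRUE)
}

# ---- Gabor receptive-field model -------------------------------------------

# One 10-parameter time-frequency Gabor component on (t ms, x oct):
# p = (K, t0, sigma_t, fm, phase_t, grad, x0, sigma_x, omega, phase_x)
# K * exp(-(t-t0)^2/2st^2) exp(-(x-x0)^2/2sx^2)
#   * cos(2 pi fm (t-t0)/1000 + grad (x-x0) + phase_t)
#   * cos(2 pi omega (x-x0) + phase_x)
# `grad` is a temporal-phase gradient along frequency that tilts the
# component, capturing oriented (FM-like) STRF structure.
gabor_component <- function(p, t_ms, x_oct) {
  dt <- t_ms - p[2]
  dx <- x_oct - p[7]
  tenv <- exp(-dt^2 / (2 * p[3]^2))
  xenv <- exp(-dx^2 / (2 * p[8]^2))
  ph <- outer(2 * pi * p[4] * dt / 1000 + p[5], p[6] * dx, `+`)
  p[1] * outer(tenv, xenv * cos(2 * pi * p[9] * dx + p[10])) * cos(ph)
}

#' Render the 20-parameter Gabor STRF model
#'
#' The model is the sum of two 10-parameter time-frequency Gabor components
#' (gain, temporal center/width/modulation frequency/phase, a temporal-phase
#' gradient along frequency, spectral center/width/ripple density/phase).
#'
#' @param params numeric vector of length 20.
#' @param t_ms lag axis in ms.
#' @param x_oct frequency axis in octaves.
#' @return lag x channel kernel matrix.
#' @export
gabor_strf <- function(params, t_ms, x_oct) {
  stopifnot(length(params) == 20)
  gabor_component(params[1:10], t_ms, x_oct) +
    gabor_component(params[11:20], t_ms, x_oct)
}

# Fit a 1-D Gabor A exp(-(g-c)^2/2s^2) cos(2 pi f (g-c) + ph) to y.
fit_gabor_1d <- function(y, g, f_scale = 1) {
  env <- abs(y)
  c0 <- sum(g * env) / sum(env)
  s0 <- sqrt(sum(env * (g - c0)^2) / sum(env)) + 1e-6
  n <- length(y)
  sp <- Mod(fft(y - mean(y)))[seq_len(ceiling(n / 2))]
  dg <- g[2] - g[1]
  f_cand <- unique(c(0, (which.max(sp) - 1) / (n * dg)))
  model <- function(p) p[1] * exp(-(g - p[2])^2 / (2 * p[3]^2)) *
    cos(2 * pi * p[4] * (g - p[2]) + p[5])
  best <- NULL
  for (f0 in f_cand) for (ph0 in c(0, pi / 2, pi, 3 * pi / 2)) {
    p0 <- c(max(env), c0, s0, f0, ph0)
    fit <- tryCatch(
      optim(p0, function(p) sum((y - model(p))^2), method = "BFGS",
            control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  best$par
}

#' Fit the 20-parameter Gabor model to a measured STRF
#'
#' Least-squares fit of the two-component Gabor STRF model: initialized from
#' a rank-2 SVD of the kernel (each singular pair fit by 1-D temporal and
#' spectral Gabors), then jointly refined with multi-start quasi-Newton
#' optimization.
#'
#' @param strf an `hsnn_strf` or a bare lag x channel matrix (then `lag_ms`
#'   and `x_oct` must be given).
#' @param n_starts number of perturbed restarts for the joint refinement.
#' @param seed seed for the restart perturbations.
#' @param lag_ms,x_oct axes when `strf` is a bare matrix.
#' @return an `hsnn_gabor_fit`: `params` (length 20), `variance_explained`,
#'   `fitted` (rendered kernel), `lag_ms`, `x_oct`, `converged`.
#' @export
fit_gabor <- function(strf, n_starts = 4, seed = 1, lag_ms = NULL,
                      x_oct = NULL) {
  if (inherits(strf, "hsnn_strf")) {
    K <- strf$kernel
    lag_ms <- strf$lag_ms
    x_oct <- (seq_len(ncol(K)) - 1) * strf$grid$spacing
  } else K <- strf
  if (is.null(lag_ms) || is.null(x_oct)) stop("axes required for bare kernels")
  ss_tot <- sum(K^2)
  if (ss_tot == 0) stop("empty STRF")
  sv <- svd(K, nu = 2, nv = 2)
  init_comp <- function(u, v, d) {
    pu <- fit_gabor_1d(u * sqrt(d), lag_ms, 1)    # temporal, fm in cyc/ms
    pv <- fit_gabor_1d(v * sqrt(d), x_oct, 1)     # spectral, omega in cyc/oct
    c(pu[1] * pv[1], pu[2], abs(pu[3]), pu[4] * 1000, pu[5], 0,
      pv[2], abs(pv[3]), pv[4], pv[5])
  }
  p1 <- init_comp(sv$u[, 1], sv$v[, 1], sv$d[1])
  resid <- K - gabor_component(p1, lag_ms, x_oct)
  sv2 <- svd(resid, nu = 1, nv = 1)
  p2 <- init_comp(sv2$u[, 1], sv2$v[, 1], sv2$d[1])
  p0 <- c(p1, p2)
  sse <- function(p) sum((K - gabor_strf(p, lag_ms, x_oct))^2)
  refine <- function(p) {
    f1 <- tryCatch(optim(p, sse, method = "Nelder-Mead",
                         control = list(maxit = 2000)),
                   error = function(e) list(par = p, value = sse(p)))
    tryCatch(optim(f1$par, sse, method = "BFGS",
                   control = list(maxit = 500)),
             error = function(e) f1)
  }
  best <- refine(p0)
  scales <- pmax(abs(p0), 0.1)
  with_seed(seed, for (s in seq_len(max(0, n_starts - 1))) {
    cand <- refine(p0 + rnorm(20, sd = 0.15 * scales))
    if (cand$value < best$value) best <- cand
  })
  ve <- 1 - best$value / ss_tot
  structure(list(params = best$par, variance_explained = ve,
                 fitted = gabor_strf(best$par, lag_ms, x_oct),
                 lag_ms = lag_ms, x_oct = x_oct,
                 converged = is.finite(best$value)),
            class = "hsnn_gabor_fit")
}

#' @export
print.hsnn_gabor_fit <- function(x, ...) {
  cat(sprintf("<hsnn_gabor_fit> 20 parameters, variance explained %.3f\n",
              x$variance_explained))
  invisible(x)
}

# ---- Mutual information (direct method) ------------------------------------

entropy_bits <- function(codes) {
  p <- tabulate(as.integer(factor(codes)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Direct-method mutual information of spike trains
#'
#' Strong-style direct estimate on a trials x time binary raster sampled at
#' `dt_ms`: the total entropy rate is estimated from the distribution of
#' binary words across time, the noise entropy rate from the across-trial
#' word distributions at fixed times, and both are extrapolated linearly in
#' inverse data fraction and inverse word length.
#'
#' @param raster_mat binary matrix, trials x time bins.
#' @param dt_ms bin width in ms (default 2).
#' @param word_lengths word lengths in bins used for the 1/L extrapolation
#'   (default 2:10); pass a single value (with `fractions = 1`) for a plain
#'   plug-in estimate.
#' @param fractions data fractions for the inverse-data-size extrapolation.
#' @param min_coverage words with fewer than `min_coverage` samples per
#'   observed state on average are flagged and dropped from the
#'   extrapolation.
#' @return list: `bits_per_s`, `bits_per_spike`, `rate` (spikes/s),
#'   `total_entropy_rate`, `noise_entropy_rate`, `word_table` (per-length
#'   estimates), `undersampled` (flag).
#' @export
mutual_information <- function(raster_mat, dt_ms = 2, word_lengths = 2:10,
                               fractions = c(1, 0.5, 0.25),
                               min_coverage = 4) {
  raster_mat <- as.matrix(raster_mat)
  n_tr <- nrow(raster_mat)
  Tn <- ncol(raster_mat)
  dt_s <- dt_ms / 1000
  rate <- mean(raster_mat) / dt_s
  word_lengths <- word_lengths[word_lengths < Tn]
  if (!length(word_lengths)) stop("word lengths exceed raster duration")
  extrap <- function(h, x) {
    if (length(unique(x)) == 1) return(h[1])
    unname(coef(lm(h ~ x))[1])
  }
  rows <- list()
  for (L in word_lengths) {
    n_start <- Tn - L + 1
    codes <- matrix(0, n_tr, n_start)
    for (j in 0:(L - 1))
      codes <- codes + raster_mat[, (1 + j):(n_start + j), drop = FALSE] * 2^j
    n_states <- length(unique(as.vector(codes)))
    # the across-trial (noise) distributions are the binding constraint:
    # require enough trials per occupied state
    covered <- n_tr / n_states >= min_coverage
    h_tot <- h_noise <- numeric(length(fractions))
    for (fi in seq_along(fractions)) {
      sub <- seq_len(max(2, round(n_tr * fractions[fi])))
      cs <- codes[sub, , drop = FALSE]
      h_tot[fi] <- entropy_bits(as.vector(cs))
      h_noise[fi] <- mean(apply(cs, 2, entropy_bits))
    }
    rows[[length(rows) + 1]] <- data.frame(
      L = L, covered = covered,
      h_total = extrap(h_tot, 1 / fractions) / (L * dt_s),
      h_noise = extrap(h_noise, 1 / fractions) / (L * dt_s))
  }
  tab <- do.call(rbind, rows)
  use <- tab[tab$covered, ]
  undersampled <- nrow(use) < nrow(tab)
  if (!nrow(use)) {
    use <- tab[1, , drop = FALSE]
    warning("all word lengths undersampled; using the shortest")
  }
  h_total <- extrap(use$h_total, 1 / use$L)
  h_noise <- extrap(use$h_noise, 1 / use$L)
  mi <- h_total - h_noise
  list(bits_per_s = mi, bits_per_spike = if (rate > 0) mi / rate else NA_real_,
       rate = rate, total_entropy_rate = h_total,
       noise_entropy_rate = h_noise, word_table = tab,
       undersampled = undersampled)
}

# ---- Response spectra and band metrics -------------------------------------

#' Welch averaged periodogram
#'
#' One-sided power spectral density with a Kaiser window (beta = 5 by
#' default), 1024-sample segments and 50% overlap. The signal is not
#' demeaned: the DC bin carries the sustained response.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param nfft segment/window length (default 1024; reduced with a message
#'   if the signal is shorter).
#' @param kaiser_beta Kaiser window shape parameter.
#' @param overlap fractional segment overlap (default 0.5).
#' @return list `freq` (Hz), `psd` (power per Hz), `enbw_hz` (equivalent
#'   noise bandwidth of the window).
#' @export
welch_psd <- function(x, fs, nfft = 1024, kaiser_beta = 5, overlap = 0.5) {
  n <- length(x)
  if (n < nfft) {
    nfft <- 2^floor(log2(n))
    message("signal shorter than the requested window; using nfft = ", nfft)
  }
  w <- signal::kaiser(nfft, kaiser_beta)
  step <- max(1, round(nfft * (1 - overlap)))
  starts <- seq(1, n - nfft + 1, by = step)
  acc <- numeric(nfft)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1)] * w
    acc <- acc + Mod(fft(seg))^2
  }
  psd <- acc / length(starts) / (fs * sum(w^2))
  half <- seq_len(nfft %/% 2 + 1)
  psd <- psd[half]
  psd[2:(length(half) - 1)] <- 2 * psd[2:(length(half) - 1)]
  list(freq = (half - 1) * fs / nfft, psd = psd,
       enbw_hz = fs * sum(w^2) / sum(w)^2)
}

#' Signal and noise response spectra across trials
#'
#' Assumes an additive model r_i(t) = s(t) + n_i(t) with trial-independent
#' noise. The trial-averaged response estimates the signal; its Welch
#' spectrum gives P_ss. Averaging the single-trial spectra gives
#' P_ss + P_nn, and the noise spectrum follows by subtraction (floored at
#' zero). SNR_output(f) = 10 log10(P_ss/P_nn), capped at `snr_ceiling_db`.
#'
#' @param rate_mat trials x time matrix of firing-rate traces (e.g. binned
#'   spike counts / bin width), >= 2 trials.
#' @param fs sampling rate of the rate traces in Hz (500 for 2 ms bins).
#' @param nfft,kaiser_beta,overlap Welch parameters (see [welch_psd()]).
#' @param snr_ceiling_db cap applied where the noise estimate underflows.
#' @return an `hsnn_response_spectra`: `freq`, `P_ss`, `P_nn`, `snr_db`,
#'   `n_trials`, `enbw_hz`.
#' @export
response_spectra <- function(rate_mat, fs, nfft = 1024, kaiser_beta = 5,
                             overlap = 0.5, snr_ceiling_db = 40) {
  rate_mat <- as.matrix(rate_mat)
  if (nrow(rate_mat) < 2) stop("need >= 2 trials to estimate the noise")
  s_hat <- colMeans(rate_mat)
  W <- welch_psd(s_hat, fs, nfft, kaiser_beta, overlap)
  p_trials <- rowMeans(vapply(seq_len(nrow(rate_mat)), function(i)
    welch_psd(rate_mat[i, ], fs, length(W$psd) * 2 - 2, kaiser_beta,
              overlap)$psd,
    numeric(length(W$psd))))
  p_nn <- pmax(p_trials - W$psd, 0)
  snr <- ifelse(p_nn > 0, 10 * log10(W$psd / p_nn), snr_ceiling_db)
  snr <- pmin(snr, snr_ceiling_db)
  structure(list(freq = W$freq, P_ss = W$psd, P_nn = p_nn, snr_db = snr,
                 n_trials = nrow(rate_mat), enbw_hz = W$enbw_hz),
            class = "hsnn_response_spectra")
}

#' Band-integrated SNR and modulation index
#'
#' Integrates SNR_output(f) over each band (trapezoid rule, reported both
#' raw in dB x Hz and bandwidth-normalized in dB), and computes the band
#' modulation index: band-integrated signal power normalized by the total
#' response power at DC.
#'
#' @param spectra an `hsnn_response_spectra`.
#' @param bands named list of c(f1, f2) ranges in Hz; defaults to the
#'   fluctuation (1-25 Hz) and periodicity-pitch (75-150 Hz) bands.
#' @return data.frame with one row per band: `band`, `f1`, `f2`,
#'   `snr_db_hz` (raw integral), `snr_db_mean`, `modulation_index`.
#' @export
band_metrics <- function(spectra,
                         bands = list(fluctuation = c(1, 25),
                                      periodicity = c(75, 150))) {
  stopifnot(inherits(spectra, "hsnn_response_spectra"))
  f <- spectra$freq
  dc_power <- spectra$P_ss[1] + spectra$P_nn[1]
  rows <- lapply(names(bands), function(nm) {
    b <- bands[[nm]]
    if (b[1] < min(f) - 1e-9 && b[1] > 0 || b[2] > max(f))
      stop("band ", nm, " outside the spectral axis")
    grid_pts <- f[f > b[1] & f < b[2]]
    xs <- c(b[1], grid_pts, b[2])
    snr_y <- approx(f, spectra$snr_db, xout = xs)$y
    pss_y <- approx(f, spectra$P_ss, xout = xs)$y
    data.frame(band = nm, f1 = b[1], f2 = b[2],
               snr_db_hz = trapz(xs, snr_y),
               snr_db_mean = trapz(xs, snr_y) / (b[2] - b[1]),
               modulation_index = trapz(xs, pss_y) / dc_power)
  })
  do.call(rbind, rows)
}

#' Layer-wise response profiles
#'
#' Summarizes per-layer firing rate and leave-one-out word accuracy from the
#' retained layer rasters of a network run over a corpus.
#'
#' @param layer_rasters list over utterances of lists over layers of
#'   `hsnn_spike_raster` (the output shape of [run_network()] applied per
#'   utterance).
#' @param labels digit labels, one per utterance.
#' @param delta_t decoder bin width in ms.
#' @param smoothing likelihood smoothing constant.
#' @return data.frame: `layer`, `rate` (spikes/s/neuron), `war` (percent).
#' @export
layer_profiles <- function(layer_rasters, labels, delta_t = 5,
                           smoothing = 0.5) {
  n_layers <- length(layer_rasters[[1]])
  duration <- max(vapply(layer_rasters, function(u) u[[1]]$duration, 1))
  do.call(rbind, lapply(seq_len(n_layers), function(l) {
    ras <- lapply(layer_rasters, `[[`, l)
    if (any(vapply(ras, is.null, TRUE))) stop("missing layer ", l)
    war <- crossval_war(lapply(ras, bin_raster, delta_t = delta_t,
                               duration = duration),
                        labels, smoothing = smoothing)
    data.frame(layer = l, rate = mean(vapply(ras, mean_rate, 1)),
               war = war$accuracy)
  }))
}
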