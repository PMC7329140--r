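#' Build a single-layer GLM network from fitted receptive fields
#'
#' One GLM neuron per output channel, each carrying the rendered Gabor-model
#' kernel of that channel's measured STRF. The LP (linear-Poisson) variant
#' drives a Poisson generator with lambda(t) = lambda0 + G * drive(t); the
#' LNP variant rectifies: lambda(t) = G * max(0, drive(t)).
#'
#' @param fits list of `hsnn_gabor_fit` (one per output channel), or a list
#'   of bare kernel matrices (lag x channel) for raw-STRF ablation.
#' @param frame_rate stimulus frame rate in Hz (kernel lag resolution).
#' @param mode "LNP" or "LP".
#' @return an `hsnn_glm_bank`: `kernels` (list), `mode`, `G`, `lambda0`,
#'   `n_neurons`, `n_parameters` (20 per fitted neuron), `frame_rate`.
#' @export
build_glm_bank <- function(fits, frame_rate = 2000, mode = c("LNP", "LP")) {
  mode <- match.arg(mode)
  if (!length(fits)) stop("no fitted channels")
  kernels <- lapply(fits, function(f) {
    if (inherits(f, "hsnn_gabor_fit")) f$fitted
    else if (is.matrix(f)) f
    else stop("unfitted channel: pass hsnn_gabor_fit objects or matrices")
  })
  n_par <- sum(vapply(fits, function(f)
    if (inherits(f, "hsnn_gabor_fit")) length(f$params) else 0L, 1L))
  structure(list(kernels = kernels, mode = mode, G = 1, lambda0 = 0,
                 n_neurons = length(kernels), n_parameters = n_par,
                 frame_rate = frame_rate),
            class = "hsnn_glm_bank")
}

#' @export
print.hsnn_glm_bank <- function(x, ...) {
  cat(sprintf("<hsnn_glm_bank> %s, %d neurons, %d parameters (G=%.3g, lambda0=%.3g)\n",
              x$mode, x$n_neurons, x$n_parameters, x$G, x$lambda0))
  invisible(x)
}

# Linear drive of every GLM neuron for one spectrogram: time x neuron matrix
# of sum_k S(., k) * kernel(., k) (causal convolution over lags), computed by
# FFT. The stimulus is centered per channel so the drive reflects
# modulations, not the DC envelope level.
glm_drive <- function(bank, spec) {
  stopifnot(inherits(spec, "hsnn_spectrogram"))
  S <- sweep(spec$values, 2, colMeans(spec$values))
  Tn <- nrow(S)
  L <- nrow(bank$kernels[[1]])
  nfft <- stats::nextn(Tn + L, 2)
  SF <- stats::mvfft(rbind(S, matrix(0, nfft - Tn, ncol(S))))
  out <- matrix(0, Tn, bank$n_neurons)
  for (m in seq_len(bank$n_neurons)) {
    K <- bank$kernels[[m]]
    KF <- stats::mvfft(rbind(K, matrix(0, nfft - L, ncol(K))))
    acc <- rowSums(Re(stats::mvfft(SF * KF, inverse = TRUE))) / nfft
    out[, m] <- acc[seq_len(Tn)]
  }
  out
}

#' Match GLM firing rates to a reference network
#'
#' Grid search over the gain G (and, for the LP network, the offset
#' lambda0) minimizing the absolute difference between the GLM's mean firing
#' rate (over all neurons and sounds) and the reference rate. LP solutions
#' must keep lambda(t) >= 0 over the whole calibration ensemble.
#'
#' @param bank an `hsnn_glm_bank`.
#' @param specs list of `hsnn_spectrogram` calibration stimuli.
#' @param target_rate reference mean rate in spikes/s (> 0), e.g. the
#'   optimal spiking network's mean output rate.
#' @param n_gain,n_offset grid resolutions (30 log-spaced gains, 20 linear
#'   offsets by default).
#' @return the bank with calibrated `G` and `lambda0` and the achieved
#'   `rate`.
#' @export
match_rates <- function(bank, specs, target_rate, n_gain = 30,
                        n_offset = 20) {
  if (target_rate <= 0) stop("target_rate must be > 0")
  drives <- lapply(specs, function(s) glm_drive(bank, s))
  all_d <- unlist(drives)
  if (bank$mode == "LNP") {
    base <- mean(pmax(all_d, 0))
    if (base <= 0) stop("all-negative drive: LNP rate is zero for any gain")
    g_ref <- target_rate / base
    G <- exp(seq(log(g_ref / 10), log(g_ref * 10), length.out = n_gain))
    err <- abs(G * base - target_rate)
    bank$G <- G[which.min(err)]
    bank$lambda0 <- 0
    bank$rate <- bank$G * base
  } else {
    d_min <- min(all_d)
    d_mean <- mean(all_d)
    g_max <- if (d_min < 0) target_rate / abs(d_min) else
      target_rate / max(abs(d_mean), 1e-9)
    G <- exp(seq(log(g_max / 300), log(g_max), length.out = n_gain))
    best <- NULL
    for (g in G) {
      l0_min <- max(0, -g * d_min) # feasibility: lambda(t) >= 0
      l0 <- seq(l0_min, l0_min + 2 * target_rate, length.out = n_offset)
      rate <- l0 + g * d_mean
      j <- which.min(abs(rate - target_rate))
      cand <- list(G = g, lambda0 = l0[j], rate = rate[j],
                   err = abs(rate[j] - target_rate))
      if (is.null(best) || cand$err < best$err) best <- cand
    }
    if (is.null(best)) stop("no feasible (G, lambda0) grid point")
    bank$G <- best$G
    bank$lambda0 <- best$lambda0
    bank$rate <- best$rate
  }
  bank
}

#' Simulate a GLM network as an inhomogeneous Poisson process
#'
#' Evaluates each neuron's rate function on the stimulus and draws spikes
#' from a discrete-time Poisson (Bernoulli thinning at the stimulus frame
#' rate), independently across neurons.
#'
#' @param bank a calibrated `hsnn_glm_bank`.
#' @param spec an `hsnn_spectrogram`.
#' @param seed integer seed.
#' @return an `hsnn_spike_raster` (times in seconds).
#' @export
glm_simulate <- function(bank, spec, seed = 1) {
  drive <- glm_drive(bank, spec)
  lambda <- if (bank$mode == "LNP") bank$G * pmax(drive, 0)
  else bank$lambda0 + bank$G * drive
  if (any(lambda < -1e-9))
    stop("negative rate reached the Poisson generator; recalibrate lambda0")
  lambda[lambda < 0] <- 0
  dt_s <- 1 / spec$frame_rate
  with_seed(seed, {
    spikes <- lapply(seq_len(ncol(lambda)), function(m) {
      n_sp <- rbinom(nrow(lambda), 1, pmin(lambda[, m] * dt_s, 1))
      (which(n_sp > 0) - 0.5) * dt_s
    })
    new_spike_raster(spikes, duration = nrow(lambda) * dt_s, dt = dt_s * 1000)
  })
}
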