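#' Power-law layer scaling rule
#'
#' The six-layer network is parameterized by the first-layer values and three
#' scaling exponents: tau_l = tau1 * alpha_tau^(l-1), sigma_l = sigma1 *
#' gamma_sigma^(l-1), N_l = N1 * lambda_N^(l-1). Defaults for the first layer
#' mimic auditory-nerve-like properties: tau1 = 0.4 ms, sigma1 = 0.0269
#' (normalized tonotopic position units), N1 = 0.5 threshold SD units.
#'
#' @param alpha_tau,gamma_sigma,lambda_N layer-to-layer scaling exponents.
#' @param tau1 first-layer membrane/EPSP time constant in ms.
#' @param sigma1 first-layer excitatory connectivity width (normalized
#'   position units).
#' @param N1 first-layer normalized threshold.
#' @param n_layers number of layers (default 6).
#' @return an `hsnn_scaling_rule`.
#' @export
scaling_rule <- function(alpha_tau = 1, gamma_sigma = 1, lambda_N = 1,
                         tau1 = 0.4, sigma1 = 0.0269, N1 = 0.5,
                         n_layers = 6) {
  for (v in c(alpha_tau, gamma_sigma, lambda_N, tau1, sigma1, N1))
    if (!is.finite(v) || v <= 0) stop("all scaling parameters must be > 0")
  structure(list(alpha_tau = alpha_tau, gamma_sigma = gamma_sigma,
                 lambda_N = lambda_N, tau1 = tau1, sigma1 = sigma1, N1 = N1,
                 n_layers = as.integer(n_layers)),
            class = "hsnn_scaling_rule")
}

#' @export
print.hsnn_scaling_rule <- function(x, ...) {
  cat(sprintf(
    "<hsnn_scaling_rule> alpha_tau=%.3g gamma_sigma=%.3g lambda_N=%.3g (tau1=%.3g ms, sigma1=%.4g, N1=%.3g, %d layers)\n",
    x$alpha_tau, x$gamma_sigma, x$lambda_N, x$tau1, x$sigma1, x$N1,
    x$n_layers))
  invisible(x)
}

# Per-layer simulation step (ms): the largest divisor of the 0.5 ms frame
# period not exceeding tau/8, so kernels are well resolved on every layer.
layer_dt <- function(tau) {
  candidates <- 0.5 / c(1, 2, 4, 5, 10, 20, 40)
  ok <- candidates <= min(0.5, tau / 8)
  if (!any(ok)) stop("layer time constant too small to discretize (tau = ",
                     tau, " ms)")
  max(candidates[ok])
}

#' Expand a scaling rule into per-layer parameters
#'
#' Applies the power-law rules and the fixed excitatory/inhibitory
#' relationships sigma_I = 1.5 sigma_E, tau_I = 1.5 tau_E, beta = 2/3.
#'
#' @param rule an [scaling_rule()].
#' @return data.frame with one row per layer: `layer`, `tau` (ms, = tau_E and
#'   the membrane time constant), `sigma` (= sigma_E), `N`, `tau_I`,
#'   `sigma_I`, `beta`, `dt` (simulation step, ms).
#' @examples
#' expand_scaling(scaling_rule(alpha_tau = 1.9))$tau
#' @export
expand_scaling <- function(rule) {
  stopifnot(inherits(rule, "hsnn_scaling_rule"))
  l <- seq_len(rule$n_layers)
  tau <- rule$tau1 * rule$alpha_tau^(l - 1)
  sigma <- rule$sigma1 * rule$gamma_sigma^(l - 1)
  N <- rule$N1 * rule$lambda_N^(l - 1)
  data.frame(layer = l, tau = tau, sigma = sigma, N = N,
             tau_I = 1.5 * tau, sigma_I = 1.5 * sigma, beta = 2 / 3,
             dt = vapply(tau, layer_dt, 1))
}

#' Fold increase of the time constant across layers
#'
#' Ratio tau_L / tau_1 implied by a scaling rule (alpha_tau^(L-1)).
#'
#' @param rule an [scaling_rule()].
#' @return numeric ratio.
#' @export
tau_fold_increase <- function(rule) {
  p <- expand_scaling(rule)
  p$tau[nrow(p)] / p$tau[1]
}

#' Scaling exponent implied by integration times at two stages
#'
#' Given integration times measured at two processing stages separated by
#' `n_steps` synaptic levels, returns the per-level scaling exponent
#' (t_far / t_near)^(1/n_steps).
#'
#' @param t_far,t_near integration times (same units) at the deeper and
#'   shallower stage.
#' @param n_steps number of intervening levels.
#' @return the implied per-level scaling exponent.
#' @examples
#' implied_scaling_exponent(4.5, 0.9, 3) # midbrain vs auditory nerve
#' @export
implied_scaling_exponent <- function(t_far, t_near, n_steps) {
  (t_far / t_near)^(1 / n_steps)
}

#' Gaussian excitatory/inhibitory connectivity matrices
#'
#' Co-tuned Gaussian profiles on normalized tonotopic positions:
#' w_{m,n} = (2 pi sigma^2)^(-1/2) exp(-(x_m - x_n)^2 / (2 sigma^2)), with
#' the inhibitory width sigma_I = 1.5 sigma_E. Profiles are truncated at
#' +/- 4 SD and left unrenormalized at the grid edges.
#'
#' @param grid a [channel_grid()] (source and target share the grid).
#' @param sigma excitatory connectivity width (normalized position units).
#' @param sigma_i inhibitory width (default `1.5 * sigma`).
#' @return list with matrices `E` and `I` (source row m, target column n).
#' @export
build_connectivity <- function(grid, sigma, sigma_i = 1.5 * sigma) {
  stopifnot(inherits(grid, "hsnn_channel_grid"))
  if (sigma <= 0 || sigma_i <= 0) stop("connectivity widths must be > 0")
  d <- outer(grid$positions, grid$positions, "-")
  gauss <- function(s) {
    w <- exp(-d^2 / (2 * s^2)) / sqrt(2 * pi * s^2)
    w[abs(d) > 4 * s] <- 0
    w
  }
  list(E = gauss(sigma), I = gauss(sigma_i))
}

#' Peak-normalized alpha-function PSP kernel
#'
#' h(t) = (t/tau) exp(1 - t/tau) for t >= 0, sampled at `dt`; peaks at
#' t = tau with value 1.
#'
#' @param tau time constant (ms).
#' @param dt sample step (ms); must satisfy dt < tau/4.
#' @param span kernel support in multiples of tau (default 8).
#' @return numeric vector h(k dt), k = 0, 1, ...
#' @export
psp_kernel <- function(tau, dt, span = 8) {
  if (dt >= tau / 4) stop("dt must be < tau/4 to resolve the kernel")
  t <- seq(0, span * tau, by = dt)
  (t / tau) * exp(1 - t / tau)
}

#' Desired membrane voltage from presynaptic drive
#'
#' Sums excitatory minus beta-weighted inhibitory convolution terms over all
#' presynaptic sources: each source's drive is convolved with the EPSP
#' (tau_E) and IPSP (tau_I = 1.5 tau_E) alpha kernels and weighted by the
#' Gaussian connectivity.
#'
#' @param drive either a time x source matrix of continuous drive (the
#'   cochlear spectrogram channels feeding layer 1), or a list of numeric
#'   spike-time vectors in ms (outputs of the previous layer).
#' @param conn connectivity list from [build_connectivity()].
#' @param tau time constant tau_E in ms (tau_I = 1.5 tau_E).
#' @param dt output sample step in ms.
#' @param beta inhibitory weighting (default 2/3).
#' @param drive_dt sample step of a continuous `drive` in ms (required for
#'   matrix drive); the drive is upsampled to `dt` by sample-and-hold.
#' @param n_steps output length (required for spike-list drive).
#' @return time x target matrix of desired voltage (arbitrary units; the
#'   network calibration fixes the scale).
#' @export
desired_voltage <- function(drive, conn, tau, dt, beta = 2 / 3,
                            drive_dt = NULL, n_steps = NULL) {
  M <- nrow(conn$E)
  if (is.matrix(drive)) {
    if (is.null(drive_dt)) stop("drive_dt required for continuous drive")
    if (ncol(drive) != M) stop("drive/connectivity shape mismatch")
    r <- drive_dt / dt
    if (abs(r - round(r)) > 1e-9) stop("drive_dt must be a multiple of dt")
    r <- as.integer(round(r))
    n <- nrow(drive) * r
    hE <- psp_kernel(tau, dt) * dt
    hI <- psp_kernel(1.5 * tau, dt) * dt
    CE <- matrix(0, n, M)
    CI <- matrix(0, n, M)
    for (m in seq_len(M)) {
      x <- rep(drive[, m], each = r)
      CE[, m] <- cpp_conv_causal(x, hE)
      CI[, m] <- cpp_conv_causal(x, hI)
    }
  } else if (is.list(drive)) {
    if (is.null(n_steps)) stop("n_steps required for spike drive")
    if (length(drive) != M) stop("drive/connectivity shape mismatch")
    n <- as.integer(n_steps)
    CE <- matrix(0, n, M)
    CI <- matrix(0, n, M)
    for (m in seq_len(M)) {
      st <- drive[[m]]
      if (length(st) == 0) next
      CE[, m] <- cpp_alpha_drive(st, tau, dt, n)
      CI[, m] <- cpp_alpha_drive(st, 1.5 * tau, dt, n)
    }
  } else stop("drive must be a matrix or a list of spike-time vectors")
  CE %*% conn$E - beta * (CI %*% conn$I)
}

#' Apply the discrete membrane filter
#'
#' Leaky integration V[k] = a V[k-1] + (1-a) I[k] with a = exp(-dt/tau),
#' the discretized exponential membrane impulse response (unit DC gain).
#'
#' @param current numeric vector or time x neuron matrix.
#' @param tau membrane time constant (ms).
#' @param dt sample step (ms).
#' @return filtered voltage, same shape as `current`.
#' @export
membrane_filter <- function(current, tau, dt) {
  a <- exp(-dt / tau)
  b <- 1 - a
  f <- function(x) as.numeric(stats::filter(b * x, a, method = "recursive"))
  if (is.matrix(current)) apply(current, 2, f) else f(current)
}

#' Derive the injected current producing a desired voltage
#'
#' Applies the exact discrete inverse of [membrane_filter()], so that
#' `membrane_filter(derive_current(v) - noise)` reproduces `v` to numerical
#' precision, then adds Gaussian white current noise at a fixed
#' signal-to-noise ratio (15 dB by default) to generate spike-timing
#' variability.
#'
#' @param v desired voltage, vector or time x neuron matrix.
#' @param tau membrane time constant (ms); must be > 0.
#' @param dt sample step (ms).
#' @param noise_snr_db current signal-to-noise ratio in dB; `Inf` disables
#'   the noise.
#' @param seed optional seed for the noise draw.
#' @return current with attribute `"noise"` holding the injected noise
#'   component (zeros when disabled).
#' @export
derive_current <- function(v, tau, dt, noise_snr_db = 15, seed = NULL) {
  if (tau <= 0 || dt <= 0) stop("tau and dt must be > 0")
  a <- exp(-dt / tau)
  b <- 1 - a
  i_sig <- if (is.matrix(v)) {
    (v - a * rbind(0, v[-nrow(v), , drop = FALSE])) / b
  } else (v - a * c(0, v[-length(v)])) / b
  noise <- i_sig * 0
  if (is.finite(noise_snr_db)) {
    noise <- with_seed(seed, {
      if (is.matrix(i_sig)) {
        s <- sqrt(colMeans(i_sig^2) / 10^(noise_snr_db / 10))
        matrix(rnorm(length(i_sig)), nrow(i_sig)) %*% diag(s, length(s))
      } else {
        rnorm(length(i_sig),
              sd = sqrt(mean(i_sig^2) / 10^(noise_snr_db / 10)))
      }
    })
  }
  structure(i_sig + noise, noise = noise)
}

new_spike_raster <- function(spikes, duration, layer = NA_integer_,
                             dt = NA_real_) {
  structure(list(spikes = spikes, n_neurons = length(spikes),
                 duration = duration, layer = layer, dt = dt),
            class = "hsnn_spike_raster")
}

#' @export
print.hsnn_spike_raster <- function(x, ...) {
  n_sp <- sum(lengths(x$spikes))
  cat(sprintf(
    "<hsnn_spike_raster> %d neurons, %.3g s, %d spikes (%.1f spikes/s/neuron)%s\n",
    x$n_neurons, x$duration, n_sp,
    n_sp / x$n_neurons / x$duration,
    if (!is.na(x$layer)) sprintf(", layer %d", x$layer) else ""))
  invisible(x)
}

#' Mean firing rate of a raster
#' @param raster an `hsnn_spike_raster`.
#' @return mean rate in spikes/s per neuron.
#' @export
mean_rate <- function(raster) {
  sum(lengths(raster$spikes)) / raster$n_neurons / raster$duration
}

#' Simulate leaky integrate-and-fire neurons
#'
#' Integrates the injected current through the discrete membrane filter;
#' a spike is emitted when the voltage (relative to rest) reaches
#' `v_thresh`, the voltage resets to rest, and an absolute refractory
#' period is imposed.
#'
#' @param current time x neuron matrix (or vector) of injected current, in
#'   the same units as voltage (unit DC gain membrane).
#' @param tau membrane time constant (ms).
#' @param dt sample step (ms).
#' @param v_thresh threshold above rest in mV (default 20 = V_T - V_r with
#'   V_T = -45, V_r = -65 mV).
#' @param refrac_ms absolute refractory period (default 1 ms).
#' @return an `hsnn_spike_raster` with spike times in seconds.
#' @export
lif_simulate <- function(current, tau, dt, v_thresh = 20, refrac_ms = 1) {
  if (!is.matrix(current)) current <- matrix(current, ncol = 1)
  a <- exp(-dt / tau)
  b <- 1 - a
  refrac_steps <- as.integer(round(refrac_ms / dt))
  spikes <- lapply(seq_len(ncol(current)), function(j) {
    r <- cpp_lif(current[, j], a, b, v_thresh, refrac_steps)
    r$spikes * dt / 1000 # seconds
  })
  new_spike_raster(spikes, duration = nrow(current) * dt / 1000, dt = dt)
}

#' Calibrate the network thresholds on a stimulus ensemble
#'
#' Runs the calibration stimuli through the network layer by layer. For each
#' layer the population standard deviation of the desired voltage is pooled
#' over neurons, time and stimuli, and a gain is fixed so that it equals
#' (V_T - V_r) / N_l = 20 mV / N_l. The gains are frozen in the returned
#' network object and reused by [run_network()].
#'
#' @param rule an [scaling_rule()].
#' @param specs list of `hsnn_spectrogram` calibration stimuli (typically ~20
#'   words at high SNR).
#' @param grid a [channel_grid()]; defaults to the grid of the first
#'   spectrogram.
#' @param seed integer seed for the calibration noise draws.
#' @param noise_snr_db injected current SNR in dB (default 15).
#' @return an `hsnn_network` with frozen per-layer gains.
#' @export
calibrate_network <- function(rule, specs, grid = NULL, seed = 1,
                              noise_snr_db = 15) {
  stopifnot(inherits(rule, "hsnn_scaling_rule"))
  if (!length(specs)) stop("calibration ensemble is empty")
  grid <- grid %||% specs[[1]]$grid
  layers <- expand_scaling(rule)
  frame_rate <- specs[[1]]$frame_rate
  frame_ms <- 1000 / frame_rate
  gains <- numeric(nrow(layers))
  conns <- lapply(seq_len(nrow(layers)), function(l)
    build_connectivity(grid, layers$sigma[l], layers$sigma_I[l]))
  # drive[[stim]] starts as the spectrogram, becomes spike lists (ms)
  drive <- lapply(specs, function(s) s$values)
  n_frames <- vapply(specs, function(s) nrow(s$values), 1L)
  for (l in seq_len(nrow(layers))) {
    dt <- layers$dt[l]
    tau <- layers$tau[l]
    vs <- vector("list", length(drive))
    for (s in seq_along(drive)) {
      vs[[s]] <- if (l == 1)
        desired_voltage(drive[[s]], conns[[l]], tau, dt,
                        drive_dt = frame_ms)
      else
        desired_voltage(drive[[s]], conns[[l]], tau, dt,
                        n_steps = round(n_frames[s] * frame_ms / dt))
    }
    sigma_v <- stats::sd(unlist(vs))
    if (!is.finite(sigma_v) || sigma_v == 0)
      stop("zero-variance population voltage in layer ", l,
           ": cannot calibrate")
    gains[l] <- (20 / layers$N[l]) / sigma_v
    for (s in seq_along(drive)) {
      i <- derive_current(gains[l] * vs[[s]], tau, dt,
                          noise_snr_db = noise_snr_db,
                          seed = child_seed(seed, l, s))
      ras <- lif_simulate(i, tau, dt)
      drive[[s]] <- lapply(ras$spikes, function(x) x * 1000) # ms
    }
  }
  structure(list(rule = rule, layers = layers, grid = grid, gains = gains,
                 noise_snr_db = noise_snr_db, frame_rate = frame_rate,
                 n_calibration = length(specs), seed = seed),
            class = "hsnn_network")
}

#' @export
print.hsnn_network <- function(x, ...) {
  cat(sprintf(
    "<hsnn_network> %d layers, %d channels; alpha_tau=%.3g gamma_sigma=%.3g lambda_N=%.3g; calibrated on %d stimuli\n",
    nrow(x$layers), x$grid$n_channels, x$rule$alpha_tau,
    x$rule$gamma_sigma, x$rule$lambda_N, x$n_calibration))
  invisible(x)
}

#' Run the spiking network on a cochlear spectrogram
#'
#' Chains desired-voltage synthesis, current derivation (deconvolution plus
#' noise), and LIF spiking across the layers, retaining the raster of every
#' layer for layer-wise analysis.
#'
#' @param net a calibrated `hsnn_network` from [calibrate_network()].
#' @param spec an `hsnn_spectrogram`.
#' @param seed integer seed for the injected current noise.
#' @return list of `hsnn_spike_raster` (one per layer, times in seconds).
#' @export
run_network <- function(net, spec, seed = 1) {
  stopifnot(inherits(net, "hsnn_network"))
  if (is.null(net$gains) || any(!is.finite(net$gains)))
    stop("network is not calibrated")
  stopifnot(inherits(spec, "hsnn_spectrogram"))
  layers <- net$layers
  frame_ms <- 1000 / spec$frame_rate
  n_frames <- nrow(spec$values)
  duration <- n_frames * frame_ms / 1000
  out <- vector("list", nrow(layers))
  drive <- spec$values
  for (l in seq_len(nrow(layers))) {
    dt <- layers$dt[l]
    tau <- layers$tau[l]
    conn <- build_connectivity(net$grid, layers$sigma[l], layers$sigma_I[l])
    v <- if (l == 1)
      desired_voltage(drive, conn, tau, dt, drive_dt = frame_ms)
    else
      desired_voltage(drive, conn, tau, dt,
                      n_steps = round(n_frames * frame_ms / dt))
    i <- derive_current(net$gains[l] * v, tau, dt,
                        noise_snr_db = net$noise_snr_db,
                        seed = child_seed(seed, l))
    ras <- lif_simulate(i, tau, dt)
    ras$layer <- l
    ras$duration <- duration
    out[[l]] <- ras
    drive <- lapply(ras$spikes, function(x) x * 1000) # ms for next layer
  }
  out
}
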