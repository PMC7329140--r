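#' Grid specification for the scaling-parameter search
#'
#' Defaults cover the full search space used for the word-recognition
#' optimization: alpha_tau 0.9-2.3, gamma_sigma 0.8-1.5, lambda_N 0.5-1.6,
#' all at 0.1 steps, evaluated at SNRs -5 to 20 dB. Reduced grids (the
#' desk-scale default for tests and examples) are supported by passing
#' shorter vectors.
#'
#' @param alpha_tau,gamma_sigma,lambda_N numeric vectors of grid values.
#' @param snr_db SNRs (dB) at which accuracy is evaluated.
#' @return an `hsnn_grid_spec` (list of the four axes).
#' @export
grid_spec <- function(alpha_tau = seq(0.9, 2.3, by = 0.1),
                      gamma_sigma = seq(0.8, 1.5, by = 0.1),
                      lambda_N = seq(0.5, 1.6, by = 0.1),
                      snr_db = c(-5, 0, 5, 10, 15, 20)) {
  if (!length(alpha_tau) || !length(gamma_sigma) || !length(lambda_N))
    stop("empty grid")
  structure(list(alpha_tau = alpha_tau, gamma_sigma = gamma_sigma,
                 lambda_N = lambda_N, snr_db = snr_db),
            class = "hsnn_grid_spec")
}

# Precompute spectrograms of a corpus mixed with babble at one SNR.
# Returns list of hsnn_spectrogram, one per utterance.
noisy_spectrograms <- function(corpus, snr_db, grid, seed,
                               frame_rate = 2000, n_babble_segments = 7) {
  lapply(seq_along(corpus$utterances), function(i) {
    u <- corpus$utterances[[i]]
    wav <- if (is.finite(snr_db)) {
      bab <- generate_babble(length(u$waveform) / u$sample_rate, corpus,
                             n_segments = n_babble_segments,
                             sample_rate = u$sample_rate,
                             seed = child_seed(seed, i, round(snr_db * 10)),
                             exclude_talker = if (corpus$design[1] > 1)
                               u$talker_id)
      mix_at_snr(u, bab, snr_db)$waveform
    } else u$waveform
    cochleagram(wav, u$sample_rate, grid, frame_rate = frame_rate)
  })
}

# Run one calibrated network over a list of spectrograms; returns the layer
# rasters for each utterance (list over utterances of lists over layers).
run_network_ensemble <- function(net, specs, seed) {
  lapply(seq_along(specs), function(i)
    run_network(net, specs[[i]], seed = child_seed(seed, i)))
}

#' Cross-validated grid search over the scaling parameters
#'
#' For every (alpha_tau, gamma_sigma, lambda_N) cell the network is
#' calibrated, run over the corpus mixed with babble at each SNR, and the
#' layer-6 rasters are scored with the leave-one-out naive-Bayes decoder.
#' Reports the per-SNR optima and the global optimum of the SNR-averaged
#' accuracy.
#'
#' @param corpus an `hsnn_corpus`.
#' @param grid an `hsnn_grid_spec` (reduced grids recommended at desk scale;
#'   the full default grid is long-running).
#' @param channel_grid_ a [channel_grid()].
#' @param delta_t decoder bin width in ms (default 5).
#' @param smoothing likelihood smoothing constant.
#' @param n_calibration number of calibration words (clean, drawn from the
#'   corpus; default min(20, corpus size)).
#' @param seed master seed; per-cell and per-utterance child seeds are
#'   derived from it, so reruns are reproducible.
#' @param frame_rate cochlear frame rate in Hz.
#' @param verbose print per-cell progress.
#' @return an `hsnn_grid_result`: `table` (one row per cell x SNR with the
#'   accuracy), `per_snr_optima`, `global_optimum`, `grid`.
#' @export
run_grid <- function(corpus, grid, channel_grid_ = channel_grid(),
                     delta_t = 5, smoothing = 0.5, n_calibration = NULL,
                     seed = 1, frame_rate = 2000, verbose = FALSE) {
  stopifnot(inherits(grid, "hsnn_grid_spec"))
  if (!length(grid$alpha_tau) || !length(grid$gamma_sigma) ||
      !length(grid$lambda_N) || !length(grid$snr_db))
    stop("empty grid")
  labels <- vapply(corpus$utterances, `[[`, 1, "digit_label")
  n_calibration <- n_calibration %||% min(20L, length(corpus$utterances))
  calib_idx <- with_seed(child_seed(seed, 999),
                         sample(seq_along(corpus$utterances), n_calibration))
  clean_specs <- lapply(corpus$utterances[calib_idx], function(u)
    cochleagram(u$waveform, u$sample_rate, channel_grid_,
                frame_rate = frame_rate))
  # spectrograms per SNR are shared across all grid cells
  specs_by_snr <- lapply(seq_along(grid$snr_db), function(si)
    noisy_spectrograms(corpus, grid$snr_db[si], channel_grid_,
                       seed = child_seed(seed, 101, si),
                       frame_rate = frame_rate))
  cells <- expand.grid(alpha_tau = grid$alpha_tau,
                       gamma_sigma = grid$gamma_sigma,
                       lambda_N = grid$lambda_N)
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    rule <- scaling_rule(cells$alpha_tau[ci], cells$gamma_sigma[ci],
                         cells$lambda_N[ci])
    net <- calibrate_network(rule, clean_specs, channel_grid_,
                             seed = child_seed(seed, ci, 1))
    for (si in seq_along(grid$snr_db)) {
      rasters <- lapply(seq_along(specs_by_snr[[si]]), function(i) {
        out <- run_network(net, specs_by_snr[[si]][[i]],
                           seed = child_seed(seed, ci, si, i))
        out[[length(out)]]
      })
      duration <- max(vapply(rasters, `[[`, 1, "duration"))
      war <- crossval_war(lapply(rasters, bin_raster, delta_t = delta_t,
                                 duration = duration),
                          labels, smoothing = smoothing)
      rows[[length(rows) + 1]] <- data.frame(
        alpha_tau = cells$alpha_tau[ci], gamma_sigma = cells$gamma_sigma[ci],
        lambda_N = cells$lambda_N[ci], snr_db = grid$snr_db[si],
        war = war$accuracy)
      if (verbose)
        message(sprintf("cell %d/%d snr %g dB: WAR %.1f%%", ci, nrow(cells),
                        grid$snr_db[si], war$accuracy))
    }
  }
  tab <- do.call(rbind, rows)
  per_snr <- do.call(rbind, lapply(split(tab, tab$snr_db), function(d)
    d[which.max(d$war), ]))
  avg <- stats::aggregate(war ~ alpha_tau + gamma_sigma + lambda_N, tab, mean)
  global <- avg[which.max(avg$war), ]
  structure(list(table = tab, per_snr_optima = per_snr,
                 global_optimum = global, mean_over_snr = avg, grid = grid,
                 seed = seed),
            class = "hsnn_grid_result")
}

#' @export
print.hsnn_grid_result <- function(x, ...) {
  g <- x$global_optimum
  cat(sprintf(
    "<hsnn_grid_result> %d cells x %d SNRs; global optimum alpha_tau=%.2g gamma_sigma=%.2g lambda_N=%.2g (mean WAR %.1f%%)\n",
    nrow(x$mean_over_snr), length(x$grid$snr_db), g$alpha_tau,
    g$gamma_sigma, g$lambda_N, g$war))
  invisible(x)
}

#' One-dimensional accuracy tuning curve along a grid axis
#'
#' Slices the grid result along `axis` with the other two scaling parameters
#' held at the global optimum, averaging accuracy over SNR.
#'
#' @param result an `hsnn_grid_result`.
#' @param axis one of "alpha_tau", "gamma_sigma", "lambda_N".
#' @return data.frame (`value`, `war`) with attributes `"peak"` (value at
#'   the maximum) and `"edge_optimum"` (TRUE if the peak sits on the grid
#'   boundary).
#' @export
marginal_curves <- function(result,
                            axis = c("alpha_tau", "gamma_sigma", "lambda_N")) {
  axis <- match.arg(axis)
  avg <- result$mean_over_snr
  others <- setdiff(c("alpha_tau", "gamma_sigma", "lambda_N"), axis)
  g <- result$global_optimum
  sel <- avg[avg[[others[1]]] == g[[others[1]]] &
               avg[[others[2]]] == g[[others[2]]], ]
  if (!nrow(sel)) stop("axis not sampled in the grid result")
  sel <- sel[order(sel[[axis]]), ]
  curve <- data.frame(value = sel[[axis]], war = sel$war)
  pk <- which.max(curve$war)
  structure(curve, peak = curve$value[pk],
            edge_optimum = pk == 1 || pk == nrow(curve))
}
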