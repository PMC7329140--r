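#' Build the cochlear channel grid
#'
#' Center frequencies are spaced at a fixed fraction of an octave starting at
#' `f_lo`: f_k = f_lo * 2^(k * spacing), k = 0..n-1. The default grid has 53
#' channels at 1/10-octave spacing covering roughly 0.1-4 kHz. Normalized
#' tonotopic positions x_k = k/(n-1) span [0, 1].
#'
#' @param f_lo lowest center frequency in Hz.
#' @param f_hi upper frequency bound in Hz (the grid must fit below it).
#' @param spacing channel spacing in octaves (default 1/10).
#' @param n_channels number of channels (default 53).
#' @return an `hsnn_channel_grid`: `center_frequencies`, `spacing`,
#'   `n_channels`, `positions` (normalized, in [0,1]).
#' @examples
#' g <- channel_grid()
#' g$center_frequencies[c(1, 11)] # 100 Hz, one octave up
#' @export
channel_grid <- function(f_lo = 100, f_hi = 4000, spacing = 1 / 10,
                         n_channels = 53) {
  if (f_lo >= f_hi) stop("f_lo must be below f_hi")
  cf <- f_lo * 2^((seq_len(n_channels) - 1) * spacing)
  if (max(cf) > f_hi)
    stop("grid cannot host ", n_channels, " channels within [f_lo, f_hi]")
  structure(list(center_frequencies = cf, spacing = spacing,
                 n_channels = as.integer(n_channels),
                 positions = (seq_len(n_channels) - 1) / (n_channels - 1)),
            class = "hsnn_channel_grid")
}

#' @export
print.hsnn_channel_grid <- function(x, ...) {
  cat(sprintf("<hsnn_channel_grid> %d channels, %.0f-%.0f Hz, %.2g oct spacing\n",
              x$n_channels, min(x$center_frequencies),
              max(x$center_frequencies), x$spacing))
  invisible(x)
}

# Equivalent rectangular bandwidth (Glasberg & Moore) in Hz.
erb_hz <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' Gammatone magnitude response
#'
#' Closed-form magnitude of the 4th-order gammatone filter at frequency `f`
#' relative to its center frequency `fc`, used by the cochlear front end and
#' as an analytic oracle in tests.
#'
#' @param f probe frequency (Hz); vectorized.
#' @param fc filter center frequency (Hz).
#' @return relative magnitude in (0, 1], equal to 1 at `f == fc`.
#' @export
gammatone_gain <- function(f, fc) {
  b <- 1.019 * erb_hz(fc)
  (b^2 / (b^2 + (f - fc)^2))^2
}

#' Cochlear spectrogram (gammatone filterbank + compressed envelopes)
#'
#' Each channel applies a 4th-order gammatone filter at its center frequency
#' with critical-band (ERB) bandwidth, extracts the envelope as the magnitude
#' of the complex (analytic) filter output, lowpass-smooths it, applies a
#' compressive power-law nonlinearity, and resamples to `frame_rate`.
#'
#' @param wave numeric waveform.
#' @param sample_rate sampling rate in Hz (must be >= 2x the top channel).
#' @param grid a [channel_grid()].
#' @param frame_rate output frame rate in Hz (default 2000); must be at least
#'   twice the envelope lowpass cutoff.
#' @param compression power-law exponent applied to the envelope
#'   (default 0.3).
#' @param env_cutoff envelope lowpass cutoff in Hz (default 750, preserving
#'   voicing-periodicity envelopes).
#' @return an `hsnn_spectrogram`: `values` (time x channel, non-negative),
#'   `frame_rate`, `grid`.
#' @export
cochleagram <- function(wave, sample_rate, grid = channel_grid(),
                        frame_rate = 2000, compression = 0.3,
                        env_cutoff = 750) {
  stopifnot(inherits(grid, "hsnn_channel_grid"))
  if (sample_rate < 2 * max(grid$center_frequencies))
    stop("sample_rate must be at least twice the top channel frequency")
  if (frame_rate < 2 * env_cutoff)
    stop("frame_rate below twice the envelope lowpass cutoff")
  if (sample_rate %% frame_rate != 0)
    stop("sample_rate must be an integer multiple of frame_rate")
  n <- length(wave)
  decim <- sample_rate %/% frame_rate
  # complex gammatone impulse responses, applied by FFT convolution; the
  # magnitude of the complex output is the channel envelope
  ir_len <- min(n, round(0.05 * sample_rate))
  tt <- (seq_len(ir_len) - 0.5) / sample_rate
  nfft <- stats::nextn(n + ir_len, 2)
  WF <- fft(c(wave, numeric(nfft - n)))
  lp <- signal::butter(2, env_cutoff / (sample_rate / 2))
  out <- matrix(0, ceiling(n / decim), grid$n_channels)
  for (k in seq_len(grid$n_channels)) {
    fc <- grid$center_frequencies[k]
    b <- 1.019 * erb_hz(fc)
    g <- tt^3 * exp(-2 * pi * b * tt) * exp(2i * pi * fc * tt)
    # normalize so a unit-amplitude tone at fc yields an envelope of ~1
    g <- g * 2 / abs(sum(g * exp(-2i * pi * fc * tt)))
    GF <- fft(c(g, complex(real = numeric(nfft - ir_len))))
    y <- fft(WF * GF, inverse = TRUE)[seq_len(n)] / nfft
    env <- Mod(y)
    env <- signal::filtfilt(lp, env)
    env[env < 0] <- 0
    env <- env^compression
    m <- matrix(c(env, numeric(nrow(out) * decim - n)), nrow = decim)
    out[, k] <- colMeans(m)
  }
  structure(list(values = out, frame_rate = frame_rate, grid = grid),
            class = "hsnn_spectrogram")
}

#' @export
print.hsnn_spectrogram <- function(x, ...) {
  cat(sprintf("<hsnn_spectrogram> %d frames x %d channels @ %g Hz (%.3g s)\n",
              nrow(x$values), ncol(x$values), x$frame_rate,
              nrow(x$values) / x$frame_rate))
  invisible(x)
}
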