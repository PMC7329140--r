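#' @section Synthetic speech:
#' The corpus generator produces digit-like words from a simple source-filter
#' recipe: a glottal pulse train (talker pitch ~80-140 Hz) excites 2-3
#' time-varying formant resonators, with broadband noise bursts standing in
#' for fricative-like segments. Digit identity is carried by a fixed
#' formant-trajectory template per digit; talker identity by pitch and a
#' vocal-tract length scaling of all formant frequencies; utterance identity
#' by small random jitter of duration, pitch and formant scale.
#' @name hsnn-stimuli
#' @keywords internal
NULL

# Formant-trajectory templates, one per digit 0-9. Durations in seconds,
# frequencies in Hz. Segment types: "v" voiced, "f" fricative, "g" gap.
digit_template <- function(digit) {
  seg <- function(type, w, f1 = NULL, f2 = NULL, f3 = NULL,
                  cf = NULL, bw = 500, amp = 1) {
    list(type = type, w = w, f1 = f1, f2 = f2, f3 = f3,
         cf = cf, bw = bw, amp = amp)
  }
  tpl <- switch(as.character(digit),
    "0" = list(dur = 0.50, segs = list(
      seg("f", 0.12, cf = 2500, amp = 0.30),
      seg("v", 0.88, f1 = c(350, 550), f2 = c(2000, 1100), f3 = c(2600, 2400)))),
    "1" = list(dur = 0.38, segs = list(
      seg("v", 1.00, f1 = c(450, 620), f2 = c(950, 1150), f3 = c(2500, 2450)))),
    "2" = list(dur = 0.34, segs = list(
      seg("f", 0.08, cf = 1800, amp = 0.50),
      seg("v", 0.92, f1 = c(330, 300), f2 = c(900, 650), f3 = c(2300, 2200)))),
    "3" = list(dur = 0.40, segs = list(
      seg("f", 0.15, cf = 2800, amp = 0.35),
      seg("v", 0.85, f1 = c(300, 280), f2 = c(2100, 2300), f3 = c(2900, 3000)))),
    "4" = list(dur = 0.46, segs = list(
      seg("f", 0.12, cf = 1200, amp = 0.25),
      seg("v", 0.88, f1 = c(550, 420), f2 = c(950, 720), f3 = c(2400, 2200)))),
    "5" = list(dur = 0.56, segs = list(
      seg("f", 0.12, cf = 1500, amp = 0.30),
      seg("v", 0.88, f1 = c(700, 320), f2 = c(1150, 2050), f3 = c(2600, 2700)))),
    "6" = list(dur = 0.52, segs = list(
      seg("f", 0.20, cf = 3300, amp = 0.45),
      seg("v", 0.50, f1 = c(320, 320), f2 = c(2150, 2050), f3 = c(2800, 2800)),
      seg("f", 0.30, cf = 3300, amp = 0.45))),
    "7" = list(dur = 0.62, segs = list(
      seg("f", 0.15, cf = 3200, amp = 0.40),
      seg("v", 0.35, f1 = c(560, 520), f2 = c(1750, 1650), f3 = c(2600, 2500)),
      seg("g", 0.10),
      seg("v", 0.40, f1 = c(480, 520), f2 = c(1300, 1500), f3 = c(2400, 2400)))),
    "8" = list(dur = 0.42, segs = list(
      seg("v", 0.60, f1 = c(520, 360), f2 = c(1850, 2250), f3 = c(2700, 2800)),
      seg("g", 0.15),
      seg("f", 0.25, cf = 2200, amp = 0.40))),
    "9" = list(dur = 0.58, segs = list(
      seg("v", 0.50, f1 = c(420, 700), f2 = c(1050, 1350), f3 = c(2500, 2550)),
      seg("v", 0.50, f1 = c(700, 420), f2 = c(1350, 1050), f3 = c(2550, 2500)))),
    stop("digit_label must be in 0..9")
  )
  tpl
}

# Glottal pulse train at time-varying f0 plus weak aspiration noise.
glottal_source <- function(f0, sr) {
  phase <- cumsum(f0 / sr)
  pulses <- c(1, diff(floor(phase))) > 0
  src <- as.numeric(pulses)
  # one-pole lowpass softens the pulses into a more glottal-like shape
  src <- as.numeric(stats::filter(src, 0.9, method = "recursive"))
  src + 0.02 * rnorm(length(f0))
}

ramp_envelope <- function(n, sr, ramp_s = 0.02) {
  nr <- max(2L, min(round(ramp_s * sr), floor(n / 2)))
  env <- rep(1, n)
  r <- (1 - cos(pi * seq_len(nr) / nr)) / 2
  env[seq_len(nr)] <- r
  env[(n - nr + 1):n] <- rev(r)
  env
}

# Synthesize one digit-like word; uses the current RNG stream for jitter.
synth_word <- function(digit, pitch_hz, vt_scale, sr) {
  tpl <- digit_template(digit)
  dur <- tpl$dur * runif(1, 0.92, 1.08)
  pitch <- pitch_hz * runif(1, 0.96, 1.04)
  fscale <- vt_scale * runif(1, 0.97, 1.03)
  out <- numeric(0)
  for (sg in tpl$segs) {
    n <- max(16L, round(sg$w * dur * sr))
    tt <- seq(0, 1, length.out = n)
    if (sg$type == "v") {
      f0 <- pitch * (1 - 0.12 * tt) # gentle declination
      src <- glottal_source(f0, sr)
      y <- numeric(n)
      amps <- c(1, 0.63, 0.32)
      bws <- c(70, 110, 170)
      for (j in 1:3) {
        fr <- sg[[paste0("f", j)]]
        if (is.null(fr)) next
        traj <- (fr[1] + (fr[2] - fr[1]) * tt) * fscale
        y <- y + amps[j] * cpp_resonator(src, traj, rep(bws[j], n), sr)
      }
      y <- y * ramp_envelope(n, sr)
    } else if (sg$type == "f") {
      noise <- rnorm(n)
      y <- sg$amp * cpp_resonator(noise, rep(sg$cf * fscale, n),
                                  rep(sg$bw, n), sr)
      y <- y * ramp_envelope(n, sr, 0.01)
      y <- y * (0.35 / max(rms(y), 1e-12)) * sg$amp
    } else { # gap
      y <- numeric(n)
    }
    if (sg$type == "v") y <- y * (0.5 / max(rms(y), 1e-12))
    out <- c(out, y)
  }
  out / max(abs(out), 1e-12) * 0.5
}

#' Generate a synthetic digit-like speech corpus
#'
#' Builds a factorial corpus of talkers x digits x utterances. Each word is
#' synthesized from a per-digit formant-trajectory template excited by a
#' glottal pulse train (voicing periodicity ~80-140 Hz per talker) with
#' noise bursts for fricative-like segments. All utterances are onset-aligned
#' (first upward crossing exceeding `threshold_sd` background SDs) to a
#' common onset position and zero-padded to a common length.
#'
#' @param n_talkers,n_digits,n_utterances factorial design counts (>= 1);
#'   `n_digits` at most 10.
#' @param sample_rate sampling rate in Hz (default 16 kHz).
#' @param seed integer seed; the corpus is a deterministic function of it.
#' @param lead_s leading/trailing background duration in seconds.
#' @param background_sd standard deviation of the low-level background noise.
#' @param threshold_sd onset threshold in background SD units.
#' @return an object of class `hsnn_corpus`: list with `utterances` (each an
#'   `hsnn_utterance` carrying `waveform`, `sample_rate`, `digit_label`,
#'   `talker_id`, `utterance_index`, `onset_sample`), `design`, `seed`,
#'   `talkers`, and `sample_rate`.
#' @examples
#' corp <- generate_corpus(1, 2, 1, seed = 1)
#' length(corp$utterances)
#' @export
generate_corpus <- function(n_talkers, n_digits, n_utterances,
                            sample_rate = 16000, seed = 1,
                            lead_s = 0.06, background_sd = 5e-4,
                            threshold_sd = 2) {
  for (v in c(n_talkers, n_digits, n_utterances)) {
    if (!is.numeric(v) || v < 1 || v != round(v))
      stop("design counts must be positive integers")
  }
  if (n_digits > 10) stop("at most 10 digits (labels 0-9)")
  talkers <- with_seed(child_seed(seed, 0), data.frame(
    talker_id = seq_len(n_talkers),
    pitch_hz = runif(n_talkers, 80, 140),
    vt_scale = runif(n_talkers, 0.90, 1.10)))
  lead_n <- round(lead_s * sample_rate)
  utts <- list()
  k <- 0
  for (t in seq_len(n_talkers)) for (d in seq_len(n_digits) - 1L)
    for (u in seq_len(n_utterances)) {
      word <- with_seed(child_seed(seed, t, d + 1, u),
                        synth_word(d, talkers$pitch_hz[t],
                                   talkers$vt_scale[t], sample_rate))
      bg <- with_seed(child_seed(seed, t, d + 1, u, 7),
                      rnorm(2 * lead_n + length(word), sd = background_sd))
      wave <- c(numeric(lead_n), word, numeric(lead_n)) + bg
      k <- k + 1
      utts[[k]] <- structure(list(
        waveform = wave, sample_rate = sample_rate, digit_label = d,
        talker_id = t, utterance_index = u, onset_sample = NA_integer_),
        class = "hsnn_utterance")
    }
  # onset alignment to a common position
  target <- lead_n + 1L
  aligned <- vector("list", length(utts))
  keep <- logical(length(utts))
  for (i in seq_along(utts)) {
    a <- tryCatch(align_onset(utts[[i]], threshold_sd = threshold_sd,
                              background_s = lead_s * 0.8,
                              target_sample = target),
                  hsnn_no_onset = function(e) NULL)
    if (is.null(a)) {
      warning("utterance ", i, " had no detectable onset; excluded")
    } else {
      aligned[[i]] <- a
      keep[i] <- TRUE
    }
  }
  aligned <- aligned[keep]
  n_max <- max(vapply(aligned, function(u) length(u$waveform), 1L))
  aligned <- lapply(aligned, function(u) {
    u$waveform <- c(u$waveform, numeric(n_max - length(u$waveform)))
    u
  })
  structure(list(utterances = aligned,
                 design = c(n_talkers = n_talkers, n_digits = n_digits,
                            n_utterances = n_utterances),
                 talkers = talkers, seed = seed, sample_rate = sample_rate),
            class = "hsnn_corpus")
}

#' @export
print.hsnn_corpus <- function(x, ...) {
  cat(sprintf(
    "<hsnn_corpus> %d utterances (%d talkers x %d digits x %d utterances), %g Hz, seed %d\n",
    length(x$utterances), x$design[1], x$design[2], x$design[3],
    x$sample_rate, x$seed))
  invisible(x)
}

#' Align an utterance on its waveform onset
#'
#' The onset is the first upward crossing of the waveform above
#' `threshold_sd` standard deviations of the leading background segment.
#' The waveform is shifted so the onset lands at `target_sample`.
#'
#' @param u an `hsnn_utterance`, or a bare numeric waveform.
#' @param threshold_sd threshold in background SD units (default 2).
#' @param background_s duration (s) of the leading segment used to estimate
#'   the background SD.
#' @param target_sample onset position after alignment (default: keep
#'   position, only record `onset_sample`).
#' @param sample_rate required if `u` is a bare waveform.
#' @return the utterance with `onset_sample` set (and waveform shifted if
#'   `target_sample` is given). Signals a condition of class `hsnn_no_onset`
#'   if no crossing exists.
#' @export
align_onset <- function(u, threshold_sd = 2, background_s = 0.05,
                        target_sample = NULL, sample_rate = NULL) {
  bare <- !inherits(u, "hsnn_utterance")
  if (bare) {
    if (is.null(sample_rate)) stop("sample_rate needed for bare waveforms")
    u <- structure(list(waveform = as.numeric(u), sample_rate = sample_rate,
                        onset_sample = NA_integer_),
                   class = "hsnn_utterance")
  }
  w <- u$waveform
  nb <- max(8L, round(background_s * u$sample_rate))
  nb <- min(nb, length(w))
  bg_sd <- stats::sd(w[seq_len(nb)])
  if (!is.finite(bg_sd) || bg_sd == 0) bg_sd <- .Machine$double.eps
  idx <- which(w > threshold_sd * bg_sd)
  if (length(idx) == 0) {
    cond <- structure(class = c("hsnn_no_onset", "error", "condition"),
                      list(message = "no onset crossing found", call = NULL))
    stop(cond)
  }
  onset <- idx[1]
  if (!is.null(target_sample)) {
    shift <- target_sample - onset
    if (shift > 0) w <- c(numeric(shift), w)
    if (shift < 0) w <- w[-seq_len(-shift)]
    u$waveform <- w
    onset <- target_sample
  }
  u$onset_sample <- as.integer(onset)
  u
}

#' Generate speech-babble noise
#'
#' Sums `n_segments` independently drawn speech-like segments (random
#' circular shifts of waveforms from `pool`, looped or cropped to
#' `duration`), then normalizes to unit RMS.
#'
#' @param duration duration in seconds (> 0).
#' @param pool list of waveform vectors (e.g. corpus utterance waveforms) or
#'   an `hsnn_corpus`.
#' @param n_segments number of summed segments (default 7).
#' @param sample_rate sampling rate in Hz.
#' @param seed integer seed.
#' @param exclude_talker optional talker id excluded from the pool when
#'   `pool` is a corpus (keeps babble talker-disjoint from the test word).
#' @param normalize normalize the sum to unit RMS (default TRUE).
#' @return numeric waveform of length `duration * sample_rate`.
#' @export
generate_babble <- function(duration, pool, n_segments = 7,
                            sample_rate = 16000, seed = 1,
                            exclude_talker = NULL, normalize = TRUE) {
  if (duration <= 0) stop("duration must be > 0")
  if (n_segments < 1) stop("n_segments must be >= 1")
  if (inherits(pool, "hsnn_corpus")) {
    utts <- pool$utterances
    if (!is.null(exclude_talker))
      utts <- Filter(function(u) u$talker_id != exclude_talker, utts)
    if (length(utts) == 0) stop("empty babble pool after talker exclusion")
    pool <- lapply(utts, `[[`, "waveform")
  }
  n <- round(duration * sample_rate)
  with_seed(seed, {
    out <- numeric(n)
    for (s in seq_len(n_segments)) {
      w <- pool[[sample.int(length(pool), 1)]]
      shift <- sample.int(length(w), 1) - 1
      w <- w[(shift + seq_len(n) - 1) %% length(w) + 1]
      out <- out + w
    }
    if (normalize) out <- out / max(rms(out), 1e-12)
    out
  })
}

#' Mix a word with noise at a prescribed SNR
#'
#' Rescales `noise` so that the signal-to-noise power ratio over the word's
#' support equals `snr_db`, then returns the additive mixture together with
#' its components.
#'
#' @param signal numeric waveform (or `hsnn_utterance`).
#' @param noise numeric noise waveform; looped/cropped to the signal length.
#' @param snr_db target SNR in dB.
#' @param support optional index range over which signal power is measured
#'   (defaults to samples from the utterance onset to the last sample above
#'   1% of peak, or the whole waveform for bare vectors).
#' @return an `hsnn_noisy` object: `waveform`, `signal`, `noise` (scaled),
#'   `snr_db`, `sample_rate` (if known). `waveform == signal + noise` exactly.
#' @export
mix_at_snr <- function(signal, noise, snr_db, support = NULL) {
  sr <- NULL
  if (inherits(signal, "hsnn_utterance")) {
    sr <- signal$sample_rate
    if (is.null(support) && !is.na(signal$onset_sample)) {
      w <- signal$waveform
      last <- max(which(abs(w) > 0.01 * max(abs(w))))
      support <- signal$onset_sample:last
    }
    signal <- signal$waveform
  }
  n <- length(signal)
  if (rms(signal) < 1e-10) stop("silent signal: SNR undefined")
  if (length(noise) < n) noise <- rep_len(noise, n)
  noise <- noise[seq_len(n)]
  if (is.null(support)) support <- seq_len(n)
  p_sig <- mean(signal[support]^2)
  p_noi <- mean(noise[support]^2)
  if (p_noi <= 0) stop("noise has zero power over the support")
  scale <- sqrt(p_sig / (p_noi * 10^(snr_db / 10)))
  noise_scaled <- noise * scale
  structure(list(waveform = signal + noise_scaled, signal = signal,
                 noise = noise_scaled, snr_db = snr_db, support = support,
                 sample_rate = sr),
            class = "hsnn_noisy")
}

#' Generate a dynamic moving ripple (DMR) probe stimulus
#'
#' A bank of log-spaced carriers on the cochlear channel grid is modulated by
#' a spectro-temporal ripple envelope whose temporal modulation rate and
#' ripple density wander slowly and uniformly over the given ranges. The
#' imposed envelope is stored for reverse-correlation receptive field
#' estimation.
#'
#' @param duration duration in seconds.
#' @param grid a [channel_grid()].
#' @param fm_range temporal modulation (ripple drift) range in Hz; the
#'   default covers both drift directions up to 350 Hz, which keeps the
#'   stimulus autocorrelation separable and unbiased for reverse
#'   correlation.
#' @param omega_range spectral modulation (ripple density) range in
#'   cycles/octave (default 0-4).
#' @param depth_db peak-to-trough modulation depth in dB (default 30).
#' @param sample_rate audio sampling rate in Hz.
#' @param frame_rate envelope sampling rate in Hz (default 2000).
#' @param fm_drift,omega_drift drift rates (Hz) of the wandering modulation
#'   parameters (random mode: breakpoint rates of the random walk).
#' @param wander "random" (default): the modulation parameters follow a
#'   seeded random walk over their ranges; "sweep": deterministic triangular
#'   scans (1 s temporal-rate period, 2.7 s density period) that cover the
#'   modulation plane uniformly — the low-discrepancy choice for short
#'   reverse-correlation probes.
#' @param phase0 initial ripple phase in radians. `phase0 = pi` yields the
#'   polarity-inverted envelope of the same stimulus, so a (0, pi) pair forms
#'   a polarity-balanced probe that cancels even-order (rectification)
#'   distortions in spike-triggered averages.
#' @param seed integer seed.
#' @param audio if FALSE, skip waveform synthesis and return only the
#'   envelope design (fast path for receptive-field simulations).
#' @return an `hsnn_dmr` object: `waveform` (or NULL), `sample_rate`,
#'   `envelope` (time x channel, zero-mean ripple in [-1, 1]), `depth_db`,
#'   `frame_rate`, `grid`, `seed`.
#' @export
generate_dmr <- function(duration, grid, fm_range = c(-350, 350),
                         omega_range = c(0, 4), depth_db = 30,
                         sample_rate = 16000, frame_rate = 2000,
                         fm_drift = 1.5, omega_drift = 3,
                         wander = c("random", "sweep"), phase0 = 0,
                         seed = 1, audio = TRUE) {
  stopifnot(inherits(grid, "hsnn_channel_grid"))
  wander <- match.arg(wander)
  if (max(abs(fm_range)) > frame_rate / 2)
    stop("temporal modulation range exceeds the envelope Nyquist rate")
  nf <- round(duration * frame_rate)
  tt <- (seq_len(nf) - 1) / frame_rate
  walk <- function(range, drift) {
    if (diff(range) == 0) return(rep(range[1], nf))
    n_bp <- max(2L, ceiling(duration * drift) + 1L)
    bp_t <- seq(0, duration, length.out = n_bp)
    bp_v <- runif(n_bp, range[1], range[2])
    approx(bp_t, bp_v, xout = tt, rule = 2)$y
  }
  triangle <- function(range, t, period) {
    ph <- (t / period) %% 1
    range[1] + diff(range) * ifelse(ph < 0.5, 2 * ph, 2 - 2 * ph)
  }
  with_seed(seed, {
    if (wander == "random") {
      fm <- walk(fm_range, fm_drift)
      om <- walk(omega_range, omega_drift)
    } else {
      fm <- triangle(fm_range, tt, 1)
      om <- triangle(omega_range, tt + 0.013, 2.7)
    }
    phase <- phase0 + 2 * pi * cumsum(fm) / frame_rate
    x_oct <- log2(grid$center_frequencies / grid$center_frequencies[1])
    env <- matrix(0, nf, grid$n_channels)
    for (k in seq_len(grid$n_channels))
      env[, k] <- sin(phase + 2 * pi * om * x_oct[k])
    wave <- NULL
    if (audio) {
      ns <- round(duration * sample_rate)
      ts <- (seq_len(ns) - 1) / sample_rate
      wave <- numeric(ns)
      car_phase <- runif(grid$n_channels, 0, 2 * pi)
      amp_db <- depth_db * (env - 1) / 2 # in [-depth, 0]
      for (k in seq_len(grid$n_channels)) {
        a <- approx(tt, 10^(amp_db[, k] / 20), xout = ts, rule = 2)$y
        wave <- wave + a * sin(2 * pi * grid$center_frequencies[k] * ts +
                                 car_phase[k])
      }
      wave <- wave / max(rms(wave), 1e-12) * 0.1
    }
    structure(list(waveform = wave, sample_rate = sample_rate,
                   envelope = env, depth_db = depth_db,
                   frame_rate = frame_rate, grid = grid,
                   fm_range = fm_range, omega_range = omega_range,
                   wander = wander, phase0 = phase0, seed = seed),
              class = "hsnn_dmr")
  })
}
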