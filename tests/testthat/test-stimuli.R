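test_that("corpus size equals the factorial design and labels are balanced", {
  corp <- generate_corpus(2, 3, 2, seed = 1)
  expect_s3_class(corp, "hsnn_corpus")
  expect_length(corp$utterances, 2 * 3 * 2)
  labels <- vapply(corp$utterances, `[[`, 1, "digit_label")
  expect_equal(as.vector(table(labels)), rep(4, 3))
  expect_true(all(labels %in% 0:9))
  # minimal design
  one <- generate_corpus(1, 1, 1, seed = 3)
  expect_length(one$utterances, 1)
  expect_equal(one$utterances[[1]]$digit_label, 0)
  expect_error(generate_corpus(0, 1, 1), "positive integers")
})

test_that("corpus generation is deterministic given the seed", {
  a <- generate_corpus(1, 2, 1, seed = 7)
  b <- generate_corpus(1, 2, 1, seed = 7)
  c <- generate_corpus(1, 2, 1, seed = 8)
  expect_identical(a$utterances[[1]]$waveform, b$utterances[[1]]$waveform)
  expect_false(identical(a$utterances[[1]]$waveform,
                         c$utterances[[1]]$waveform))
})

test_that("different digits have distinct spectro-temporal templates", {
  corp <- generate_corpus(1, 10, 1, seed = 2)
  sp <- lapply(corp$utterances, function(u)
    colMeans(cochleagram(u$waveform, u$sample_rate, fx_grid())$values))
  # pairwise correlation of mean spectra below 1 for all digit pairs
  for (i in 1:9) for (j in (i + 1):10)
    expect_lt(cor(sp[[i]], sp[[j]]), 0.999)
  # all utterances onset-aligned to a common position
  onsets <- vapply(corp$utterances, `[[`, 1L, "onset_sample")
  expect_length(unique(onsets), 1)
})

test_that("talkers differ in voicing pitch within the 80-140 Hz range", {
  corp <- generate_corpus(4, 1, 1, seed = 9)
  expect_true(all(corp$talkers$pitch_hz >= 80 & corp$talkers$pitch_hz <= 140))
  expect_gt(length(unique(round(corp$talkers$pitch_hz))), 1)
})

test_that("babble is unit RMS and segment variances add independently", {
  corp <- fx_corpus_small()
  bab <- generate_babble(0.5, corp, n_segments = 7, seed = 1)
  expect_equal(sqrt(mean(bab^2)), 1, tolerance = 1e-10)
  expect_length(bab, 0.5 * 16000)
  one <- generate_babble(0.5, corp, n_segments = 1, seed = 2)
  expect_equal(sqrt(mean(one^2)), 1, tolerance = 1e-10)
  expect_error(generate_babble(-1, corp), "duration")
  # Monte-Carlo: variance of an n-segment sum (before normalization) grows
  # approximately linearly with n for independently drawn segments
  v1 <- vapply(1:100, function(s)
    var(generate_babble(0.4, corp, 1, seed = s, normalize = FALSE)), 1)
  v7 <- vapply(1:100, function(s)
    var(generate_babble(0.4, corp, 7, seed = 1000 + s, normalize = FALSE)), 1)
  expect_equal(mean(v7) / mean(v1), 7, tolerance = 0.35)
})

test_that("mix_at_snr hits the requested SNR and reconstructs additively", {
  set.seed(4)
  signal <- sin(2 * pi * 300 * seq(0, 0.3, by = 1 / 8000))
  noise <- rnorm(length(signal))
  for (snr in c(-5, 0, 5, 10, 15, 20)) {
    mx <- mix_at_snr(signal, noise, snr)
    realized <- 10 * log10(mean(mx$signal^2) / mean(mx$noise^2))
    expect_equal(realized, snr, tolerance = 0.1)
    expect_identical(mx$waveform, mx$signal + mx$noise)
  }
  mx0 <- mix_at_snr(signal, noise, 20)
  expect_equal(mean(mx0$signal^2) / mean(mx0$noise^2), 100, tolerance = 1e-6)
  expect_error(mix_at_snr(numeric(100), noise[1:100], 0), "silent")
})

test_that("onset alignment finds the first threshold crossing", {
  sr <- 8000
  set.seed(5)
  bg <- rnorm(sr, sd = 1e-3)
  k <- 4001
  w <- bg
  w[k:length(w)] <- w[k:length(w)] + 10e-3 # 10 SD step
  u <- align_onset(w, sample_rate = sr)
  expect_equal(u$onset_sample, k, tolerance = 3)
  # ramp crossing 2 SD at a known sample (scan oracle)
  ramp <- bg
  ramp[4001:8000] <- ramp[4001:8000] + seq(0, 8e-3, length.out = 4000)
  sd_bg <- sd(ramp[1:round(0.05 * sr)])
  oracle <- which(ramp > 2 * sd_bg)[1]
  expect_equal(align_onset(ramp, sample_rate = sr)$onset_sample, oracle)
  # pure silence has no onset
  expect_error(align_onset(numeric(1000) , sample_rate = sr),
               class = "hsnn_no_onset")
})

test_that("DMR degenerates to the analytic ripple and is unbiased", {
  g <- fx_grid()
  # fixed (non-wandering) ripple: 1 cyc/oct at 10 Hz
  dmr <- generate_dmr(0.5, g, fm_range = c(10, 10), omega_range = c(1, 1),
                      seed = 1, audio = FALSE)
  tt <- (seq_len(nrow(dmr$envelope)) - 1) / dmr$frame_rate
  x_oct <- log2(g$center_frequencies / g$center_frequencies[1])
  analytic <- sin(2 * pi * 10 * tt + 2 * pi * 1 * x_oct[20])
  # phase accumulates from the first frame; allow a one-frame offset
  expect_gt(cor(dmr$envelope[, 20], analytic), 0.999)
  # unbiased: long-run channel-mean linear envelope flat within 5%
  long <- generate_dmr(60, g, seed = 2, audio = FALSE)
  ch_mean <- colMeans(10^(long$depth_db * (long$envelope - 1) / 2 / 20))
  expect_lt((max(ch_mean) - min(ch_mean)) / mean(ch_mean), 0.05)
  # determinism and Nyquist guard
  again <- generate_dmr(0.5, g, fm_range = c(10, 10), omega_range = c(1, 1),
                        seed = 1, audio = FALSE)
  expect_identical(dmr$envelope, again$envelope)
  expect_error(generate_dmr(1, g, fm_range = c(0, 1500), audio = FALSE),
               "Nyquist")
})

test_that("WAV round trip preserves waveforms", {
  set.seed(6)
  w <- runif(2000, -0.9, 0.9)
  f16 <- tempfile(fileext = ".wav")
  f32 <- tempfile(fileext = ".wav")
  write_wav(w, 16000, f16, bits = 16)
  write_wav(w, 16000, f32, bits = 32)
  r16 <- read_wav(f16)
  r32 <- read_wav(f32)
  expect_equal(r16$sample_rate, 16000)
  expect_equal(r16$wave, w, tolerance = 1e-4)
  expect_equal(r32$wave, w, tolerance = 1e-7)
  unlink(c(f16, f32))
})
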