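#' Write a waveform to a WAV file
#'
#' Minimal RIFF/WAVE writer supporting 16-bit PCM and 32-bit IEEE float,
#' mono. Amplitudes are expected in [-1, 1]; PCM output is clipped.
#'
#' @param wave numeric vector of samples in [-1, 1].
#' @param sample_rate sampling rate in Hz.
#' @param path output file path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, sample_rate, path, bits = 16) {
  if (!bits %in% c(16, 32)) stop("bits must be 16 or 32")
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(wave)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  fmt <- if (bits == 16) 1L else 3L # PCM vs IEEE float
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16) {
    x <- pmin(pmax(wave, -1), 1)
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(wave), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Reads mono 16-bit PCM or 32-bit IEEE float WAV files written by
#' [write_wav()] (and standard files of those formats).
#'
#' @param path file path.
#' @return list with `wave` (numeric, [-1, 1] for PCM) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  wave_tag <- readChar(con, 4)
  if (!identical(wave_tag, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; sr <- NULL; bits <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", size = 2, endian = "little")
      n_chan <- readBin(con, "integer", size = 2, endian = "little")
      if (n_chan != 1) stop("only mono WAV supported")
      sr <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "integer", size = 4, endian = "little"))
      invisible(readBin(con, "integer", size = 2, endian = "little"))
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", n = size - 16))
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV: data before fmt")
      if (bits == 16) {
        data <- readBin(con, "integer", n = size / 2, size = 2,
                        endian = "little") / 32767
      } else if (bits == 32 && fmt == 3) {
        data <- readBin(con, "numeric", n = size / 4, size = 4,
                        endian = "little")
      } else stop("unsupported WAV encoding (", bits, " bit, fmt ", fmt, ")")
      break
    } else {
      invisible(readBin(con, "raw", n = size))
    }
  }
  if (is.null(data)) stop("no data chunk found in ", path)
  list(wave = as.numeric(data), sample_rate = sr)
}

#' Write a corpus manifest
#'
#' Writes per-utterance metadata (file, digit, talker, utterance index,
#' onset sample) as CSV alongside optional WAV export of every utterance.
#'
#' @param corpus a `hsnn_corpus`.
#' @param dir output directory (created if needed).
#' @param write_audio also write one WAV per utterance.
#' @return path of the manifest CSV, invisibly.
#' @export
write_corpus <- function(corpus, dir, write_audio = TRUE) {
  stopifnot(inherits(corpus, "hsnn_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(corpus$utterances), function(i) {
    u <- corpus$utterances[[i]]
    fn <- sprintf("d%d_t%d_u%d.wav", u$digit_label, u$talker_id,
                  u$utterance_index)
    if (write_audio) write_wav(u$waveform, u$sample_rate, file.path(dir, fn))
    data.frame(file = fn, digit = u$digit_label, talker = u$talker_id,
               utterance = u$utterance_index, onset_sample = u$onset_sample,
               sample_rate = u$sample_rate)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
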