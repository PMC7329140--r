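#' @useDynLib hsnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif fft filter approx optim sd coef lm rbinom
#' @importFrom utils head tail write.csv
NULL

# Derive a reproducible child seed from a master seed and integer indices.
# Keeps results below 2^31 so they remain valid R integer seeds.
child_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (i in seq_along(idx)) {
    s <- (s * 48271 + as.double(idx[i]) * 1009 + i * 97) %% 2147483647
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# Trapezoidal integration.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

rms <- function(x) sqrt(mean(x^2))

# Root-mean-square power in dB relative terms.
power_db_ratio <- function(a, b) 10 * log10(mean(a^2) / mean(b^2))

# Small stable content hash (FNV-1a over the serialized object), used to tag
# experiment outputs with their configuration.
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
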