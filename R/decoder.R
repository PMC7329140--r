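#' Bin a spike raster into a binary response matrix
#'
#' r_{n,i} = 1 iff neuron n fired at least one spike in
#' [ (i-1) dt, i dt ) — presence/absence, not counts.
#'
#' @param raster an `hsnn_spike_raster` (times in seconds).
#' @param delta_t bin width in ms (0.5-100).
#' @param duration response window in seconds (default: raster duration);
#'   spikes beyond it are dropped, shorter responses are zero-padded.
#' @return an `hsnn_binned`: binary matrix `R` (neurons x bins), `delta_t`
#'   (ms), `duration`.
#' @export
bin_raster <- function(raster, delta_t, duration = NULL) {
  stopifnot(inherits(raster, "hsnn_spike_raster"))
  if (!is.numeric(delta_t) || delta_t <= 0) stop("delta_t must be > 0")
  duration <- duration %||% raster$duration
  dt_s <- delta_t / 1000
  M <- ceiling(duration / dt_s)
  R <- matrix(0L, raster$n_neurons, M)
  for (n in seq_len(raster$n_neurons)) {
    st <- raster$spikes[[n]]
    st <- st[st >= 0 & st < duration]
    if (length(st)) R[n, unique(pmin(M, floor(st / dt_s) + 1L))] <- 1L
  }
  structure(list(R = R, delta_t = delta_t, duration = duration),
            class = "hsnn_binned")
}

#' Fit Bernoulli naive-Bayes likelihood tables
#'
#' For each digit class d, neuron n and time bin i, the likelihood of a spike
#' is the smoothed empirical firing probability
#' p_{d,n,i} = (k + a) / (T_d + 2a), where k is the number of training
#' responses of digit d with a spike at (n, i) and a > 0 is the smoothing
#' constant (Jeffreys a = 0.5 by default).
#'
#' @param responses list of `hsnn_binned` (or bare binary matrices) with a
#'   common shape.
#' @param labels integer class labels (digits), one per response.
#' @param smoothing additive smoothing constant a > 0.
#' @return an `hsnn_likelihood`: array `p` (class x neuron x bin) with
#'   dimnames on the class axis, `classes`, `smoothing`, `delta_t`.
#' @export
fit_likelihood <- function(responses, labels, smoothing = 0.5) {
  if (smoothing <= 0) stop("smoothing must be > 0")
  if (length(responses) != length(labels)) stop("length mismatch")
  mats <- lapply(responses, function(r) if (inherits(r, "hsnn_binned")) r$R else r)
  dims <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), dims), TRUE)))
    stop("responses must share a common (neurons x bins) shape")
  classes <- sort(unique(labels))
  p <- array(0, c(length(classes), dims[1], dims[2]),
             dimnames = list(class = classes, NULL, NULL))
  for (ci in seq_along(classes)) {
    idx <- which(labels == classes[ci])
    K <- Reduce(`+`, mats[idx])
    p[ci, , ] <- (K + smoothing) / (length(idx) + 2 * smoothing)
  }
  delta_t <- if (inherits(responses[[1]], "hsnn_binned"))
    responses[[1]]$delta_t else NA_real_
  structure(list(p = p, classes = classes, smoothing = smoothing,
                 delta_t = delta_t),
            class = "hsnn_likelihood")
}

# Log-likelihood of a binary response matrix under each class.
binned_loglik <- function(R, table) {
  vapply(seq_along(table$classes), function(ci) {
    p <- table$p[ci, , ]
    sum(R * log(p) + (1 - R) * log1p(-p))
  }, 1)
}

#' Classify a binned response with the naive-Bayes reader
#'
#' Evaluates, in the log domain, the Bernoulli product
#' prod_{n,i} p^{r} (1-p)^{1-r} for each class and returns the argmax.
#' Ties are broken toward the lowest class label (recorded in the `"tie"`
#' attribute).
#'
#' @param response an `hsnn_binned` or binary matrix matching the table.
#' @param table an `hsnn_likelihood` from [fit_likelihood()].
#' @return the winning class label, with attributes `"loglik"` (named vector)
#'   and `"tie"` (logical).
#' @export
classify_response <- function(response, table) {
  R <- if (inherits(response, "hsnn_binned")) response$R else response
  if (!identical(dim(R), dim(table$p)[2:3])) stop("shape mismatch")
  ll <- binned_loglik(R, table)
  best <- which(ll == max(ll))
  structure(table$classes[best[1]],
            loglik = stats::setNames(ll, table$classes),
            tie = length(best) > 1)
}

#' Leave-one-out cross-validated word accuracy rate (WAR)
#'
#' For each utterance, the likelihood tables are trained on all remaining
#' utterances and the held-out response is classified; WAR is the percentage
#' of correct folds. Class counts are updated incrementally, so the full
#' leave-one-out loop costs one pass over the data.
#'
#' @param responses list of `hsnn_binned` (or binary matrices), common shape.
#' @param labels integer class labels; every class needs >= 2 utterances.
#' @param smoothing additive smoothing constant (default 0.5).
#' @return an `hsnn_war`: `accuracy` (percent), `confusion`
#'   (true x predicted counts), `n_folds`, `per_fold` (0/100 vector),
#'   `delta_t`.
#' @export
crossval_war <- function(responses, labels, smoothing = 0.5) {
  mats <- lapply(responses, function(r) if (inherits(r, "hsnn_binned")) r$R else r)
  classes <- sort(unique(labels))
  tab <- table(factor(labels, levels = classes))
  if (any(tab < 2))
    stop("every class needs at least 2 utterances for leave-one-out")
  counts <- lapply(classes, function(cl)
    Reduce(`+`, mats[labels == cl]))
  names(counts) <- as.character(classes)
  n_per <- as.numeric(tab)
  names(n_per) <- as.character(classes)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  per_fold <- numeric(length(mats))
  for (i in seq_along(mats)) {
    R <- mats[[i]]
    lab <- as.character(labels[i])
    ll <- vapply(as.character(classes), function(cl) {
      K <- counts[[cl]]
      Tn <- n_per[[cl]]
      if (cl == lab) { K <- K - R; Tn <- Tn - 1 }
      p <- (K + smoothing) / (Tn + 2 * smoothing)
      sum(R * log(p) + (1 - R) * log1p(-p))
    }, 1)
    pred <- classes[which.max(ll)] # which.max breaks ties to lowest label
    confusion[lab, as.character(pred)] <- confusion[lab, as.character(pred)] + 1L
    per_fold[i] <- if (pred == labels[i]) 100 else 0
  }
  structure(list(accuracy = mean(per_fold), confusion = confusion,
                 n_folds = length(mats), per_fold = per_fold,
                 delta_t = if (inherits(responses[[1]], "hsnn_binned"))
                   responses[[1]]$delta_t else NA_real_),
            class = "hsnn_war")
}

#' @export
print.hsnn_war <- function(x, ...) {
  cat(sprintf("<hsnn_war> accuracy %.1f%% over %d leave-one-out folds\n",
              x$accuracy, x$n_folds))
  invisible(x)
}

#' Word accuracy as a function of spike-timing resolution
#'
#' Re-bins fixed rasters at each requested resolution and re-runs the
#' leave-one-out decoder, tracing out the accuracy-versus-resolution curve.
#'
#' @param rasters list of `hsnn_spike_raster`, one per utterance.
#' @param labels integer class labels.
#' @param delta_t_ms vector of bin widths in ms (default 0.5-100, log-ish).
#' @param duration common response window in seconds (default: max raster
#'   duration).
#' @param smoothing likelihood smoothing constant.
#' @return data.frame with columns `delta_t` and `war`, plus attributes
#'   `"optimum"` (the argmax delta_t) and `"war_results"`.
#' @export
resolution_sweep <- function(rasters, labels,
                             delta_t_ms = c(0.5, 1, 2, 5, 10, 20, 50, 100),
                             duration = NULL, smoothing = 0.5) {
  if (!length(delta_t_ms)) stop("empty delta_t list")
  duration <- duration %||% max(vapply(rasters, `[[`, 1, "duration"))
  results <- lapply(delta_t_ms, function(dt) {
    crossval_war(lapply(rasters, bin_raster, delta_t = dt,
                        duration = duration),
                 labels, smoothing = smoothing)
  })
  curve <- data.frame(delta_t = delta_t_ms,
                      war = vapply(results, `[[`, 1, "accuracy"))
  structure(curve, optimum = delta_t_ms[which.max(curve$war)],
            war_results = results)
}
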