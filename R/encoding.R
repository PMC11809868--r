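#' Construct a confidence curve
#'
#' A per-sample event-likelihood series for one (side, event-type) stream.
#' Encoder output lies in \[0, 1\]; model or fused output may slightly
#' exceed that range but must be finite.
#'
#' @param values Numeric vector of confidence values.
#' @param rate_hz Sampling rate (Hz).
#' @param side `"L"` or `"R"`.
#' @param type `"HS"` or `"TO"`.
#' @param sigma_ms Gaussian width used by the encoder (ms).
#' @return An object of class `gait_curve`.
#' @export
gait_curve <- function(values, rate_hz, side = "L", type = "HS", sigma_ms = 53.3) {
  values <- as.numeric(values)
  if (any(!is.finite(values)))
    stop("confidence values must be finite", call. = FALSE)
  stopifnot(rate_hz > 0, side %in% c("L", "R"), type %in% c("HS", "TO"),
            sigma_ms > 0)
  structure(list(values = values, rate_hz = as.numeric(rate_hz),
                 side = side, type = type, sigma_ms = as.numeric(sigma_ms)),
            class = "gait_curve")
}

#' @export
print.gait_curve <- function(x, ...) {
  cat(sprintf("<gait_curve> %s %s: %d samples @ %g Hz, range [%.3g, %.3g]\n",
              x$side, x$type, length(x$values), x$rate_hz,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.gait_curve <- function(x) length(x$values)

#' Encode event times as a Gaussian confidence curve
#'
#' Each event contributes a Gaussian bump of peak 1 and standard deviation
#' `sigma_ms` centered on the event; the curve is 0 between events.  The
#' Gaussian support is truncated at 4 sigma (value < 4e-4 at the cut, far
#' below decoding relevance); where supports of neighbouring events would
#' overlap, the elementwise maximum is taken so peaks stay at 1.
#'
#' @param events A [gait_events()] set; the (`side`, `type`) stream is
#'   encoded.
#' @param n_samples Length of the output curve.
#' @param rate_hz Sampling rate of the output curve (Hz).
#' @param sigma_ms Gaussian standard deviation in ms (default 53.3).
#' @param side,type Which event stream to encode.
#' @return A [gait_curve()] of length `n_samples`.
#' @export
encode_events <- function(events, n_samples, rate_hz, sigma_ms = 53.3,
                          side = "L", type = "HS") {
  stopifnot(sigma_ms > 0, n_samples >= 1, rate_hz > 0)
  times <- event_stream(events, side, type)
  dur_ms <- n_samples / rate_hz * 1000
  if (length(times) && (any(times < 0) || any(times > dur_ms)))
    stop(sprintf("event outside the encoded window [0, %.6g] ms", dur_ms),
         call. = FALSE)
  t_ms <- (seq_len(n_samples) - 1) / rate_hz * 1000
  v <- numeric(n_samples)
  half <- 4 * sigma_ms
  for (e in times) {
    lo <- which(t_ms >= e - half)[1]
    hi_cand <- which(t_ms > e + half)
    hi <- if (length(hi_cand)) hi_cand[1] - 1L else n_samples
    if (is.na(lo) || lo > hi) next
    idx <- lo:hi
    v[idx] <- pmax(v[idx], exp(-(t_ms[idx] - e)^2 / (2 * sigma_ms^2)))
  }
  gait_curve(v, rate_hz, side, type, sigma_ms)
}

#' Decode events from a confidence curve by constrained peak detection
#'
#' Local maxima at least `min_height` high are accepted greedily in
#' descending height order; a candidate within `min_interval_ms` of an
#' already accepted peak is rejected (the MATLAB `findpeaks`
#' minimum-peak-distance semantics the method was built on).  Equal heights
#' are broken in favour of the earlier peak; plateau maxima report the
#' plateau center.  Endpoint samples are not considered peaks.
#'
#' @param curve A [gait_curve()].
#' @param min_height Minimum peak height (default 0.3).
#' @param min_interval_ms Minimum spacing between accepted peaks in ms
#'   (default 1000).
#' @return A [gait_events()] set (source `"model"`) carrying the curve's
#'   side and type.
#' @export
decode_peaks <- function(curve, min_height = 0.3, min_interval_ms = 1000) {
  stopifnot(inherits(curve, "gait_curve"))
  v <- curve$values
  n <- length(v)
  cand_idx <- integer(0)
  if (n >= 3L) {
    # run-length encode so plateaus count once, at their center
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- length(r$values)
    if (k >= 3L) {
      is_max <- logical(k)
      for (j in 2:(k - 1L))
        is_max[j] <- r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]
      sel <- which(is_max & r$values >= min_height)
      cand_idx <- (starts[sel] + ends[sel]) %/% 2L
    }
  }
  if (length(cand_idx)) {
    h <- v[cand_idx]
    ord <- order(-h, cand_idx)
    min_gap <- min_interval_ms / 1000 * curve$rate_hz
    accepted <- integer(0)
    for (i in cand_idx[ord]) {
      if (!length(accepted) || all(abs(accepted - i) >= min_gap))
        accepted <- c(accepted, i)
    }
    accepted <- sort(accepted)
  } else accepted <- integer(0)
  gait_events(rep(curve$side, length(accepted)),
              rep(curve$type, length(accepted)),
              (accepted - 1) / curve$rate_hz * 1000,
              source = "model")
}

#' Pearson correlation between two confidence curves
#'
#' The model-selection criterion used when tuning network hyperparameters:
#' the correlation between a predicted curve and the manually derived one.
#'
#' @param a,b [gait_curve()]s of equal length (>= 2), non-constant.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
curve_correlation <- function(a, b) {
  stopifnot(inherits(a, "gait_curve"), inherits(b, "gait_curve"))
  if (length(a$values) != length(b$values))
    stop("curves must have equal length", call. = FALSE)
  if (length(a$values) < 2L)
    stop("curves must contain at least 2 samples", call. = FALSE)
  if (stats::sd(a$values) == 0 || stats::sd(b$values) == 0)
    stop("correlation is undefined for a constant curve", call. = FALSE)
  stats::cor(a$values, b$values)
}
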