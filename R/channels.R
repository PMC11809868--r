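#' Construct a signal channel
#'
#' A channel is one uniformly sampled time series belonging to a walking
#' trial: either a vertical ground reaction force (N) or a heel marker
#' height (mm).
#'
#' @param values Numeric vector of samples (length >= 2, no missing values;
#'   marker gap filling is out of scope, inputs must be complete).
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param kind `"grf_vertical"` or `"heel_height"`.
#' @return An object of class `gait_channel`.
#' @export
gait_channel <- function(values, rate_hz, kind = c("grf_vertical", "heel_height")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("channel must contain at least 2 samples", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("channel contains missing or non-finite samples; inputs must be gap-free",
         call. = FALSE)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a single positive number", call. = FALSE)
  structure(list(values = values, rate_hz = as.numeric(rate_hz), kind = kind),
            class = "gait_channel")
}

#' @export
print.gait_channel <- function(x, ...) {
  cat(sprintf("<gait_channel> %s: %d samples @ %g Hz (%.1f s)\n",
              x$kind, length(x$values), x$rate_hz,
              length(x$values) / x$rate_hz))
  invisible(x)
}

#' @export
length.gait_channel <- function(x) length(x$values)

#' Sample times of a channel in milliseconds
#' @param channel A `gait_channel`.
#' @return Numeric vector of sample times (ms), starting at 0.
#' @export
channel_times_ms <- function(channel) {
  stopifnot(inherits(channel, "gait_channel"))
  (seq_along(channel$values) - 1) / channel$rate_hz * 1000
}

#' Construct a walking trial record
#'
#' Bundles the four signals of one treadmill trial: left/right vertical GRF
#' and left/right heel marker height, together with the subject's body
#' weight.  Channels may be at their native rates (GRF typically 1000 Hz,
#' markers 100 Hz) before [preprocess_trial()] brings them onto a common
#' grid.
#'
#' @param trial_id Character identifier.
#' @param body_weight_N Subject body weight in newtons (> 0).
#' @param grf_left,grf_right `gait_channel`s of kind `"grf_vertical"`.
#' @param heel_left,heel_right `gait_channel`s of kind `"heel_height"`.
#' @param condition `"no_exo"` or `"exo"`.
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(trial_id, body_weight_N, grf_left, grf_right,
                       heel_left, heel_right, condition = c("no_exo", "exo")) {
  condition <- match.arg(condition)
  if (!is.numeric(body_weight_N) || length(body_weight_N) != 1L || body_weight_N <= 0)
    stop("body_weight_N must be a single positive number", call. = FALSE)
  chans <- list(grf_left = grf_left, grf_right = grf_right,
                heel_left = heel_left, heel_right = heel_right)
  for (nm in names(chans)) {
    ch <- chans[[nm]]
    if (!inherits(ch, "gait_channel"))
      stop(sprintf("'%s' must be a gait_channel", nm), call. = FALSE)
    want <- if (grepl("^grf", nm)) "grf_vertical" else "heel_height"
    if (ch$kind != want)
      stop(sprintf("'%s' must have kind '%s'", nm, want), call. = FALSE)
  }
  rates <- vapply(chans, function(ch) ch$rate_hz, numeric(1))
  common <- if (length(unique(rates)) == 1L) rates[[1]] else NA_real_
  structure(list(trial_id = as.character(trial_id),
                 body_weight_N = as.numeric(body_weight_N),
                 condition = condition,
                 channels = chans,
                 rate_hz = common),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> '%s' (%s), body weight %.1f N\n",
              x$trial_id, x$condition, x$body_weight_N))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-10s %6d samples @ %g Hz\n", nm, length(ch$values), ch$rate_hz))
  }
  invisible(x)
}
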