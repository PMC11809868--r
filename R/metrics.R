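#' Match detected events to reference events
#'
#' Pairs each reference ("manual") event with the closest detected event of
#' the same stream; detected events may be reused, so the pairing follows
#' the per-reference-event definition used for all timing statistics.
#' Equidistant candidates resolve to the earlier detected event.  The error
#' sign convention is `detected - reference`: positive means the reference
#' event was earlier.
#'
#' @param model Numeric vector of detected event times (ms) for one
#'   (side, type) stream, or a [gait_events()] set (then `side`/`type`
#'   select the stream).
#' @param manual Reference event times for the same stream (same types as
#'   `model`).
#' @param side,type Stream selector when event sets are given.
#' @return A data frame of class `event_matches` with columns
#'   `manual_time_ms`, `model_time_ms` (NA when no detected event exists),
#'   and `error_ms`.
#' @export
match_events <- function(model, manual, side = "L", type = "HS") {
  mt <- if (inherits(model, "gait_events")) event_stream(model, side, type) else sort(as.numeric(model))
  rt <- if (inherits(manual, "gait_events")) event_stream(manual, side, type) else sort(as.numeric(manual))
  if (!length(rt))
    return(structure(data.frame(manual_time_ms = numeric(0),
                                model_time_ms = numeric(0),
                                error_ms = numeric(0)),
                     class = c("event_matches", "data.frame")))
  if (!length(mt)) {
    out <- data.frame(manual_time_ms = rt, model_time_ms = NA_real_,
                      error_ms = NA_real_)
  } else {
    nearest <- vapply(rt, function(m) {
      d <- abs(mt - m)
      mt[which.min(d)]  # which.min takes the first (earlier) on ties
    }, numeric(1))
    out <- data.frame(manual_time_ms = rt, model_time_ms = nearest,
                      error_ms = nearest - rt)
  }
  structure(out, class = c("event_matches", "data.frame"))
}

#' Event-timing error report
#'
#' Computes the evaluation bundle for a set of event matches: mean error
#' (ME), median absolute error (MAE), interquartile range of the signed
#' error (IQR), standard deviation over successful detections only (SD),
#' maximum absolute error (MAX), successful detection rate (SR, reference
#' events with a detected event within `sr_window_ms`), and overall
#' detection rate (DR, within `dr_window_ms`).  Window comparisons are
#' inclusive.  Reference events without any detected event count as
#' failures for SR and DR and are excluded from ME/MAE/IQR/MAX; SD is the
#' sample (n-1) standard deviation.
#'
#' @param matches An `event_matches` data frame from [match_events()], or a
#'   list of them (pooled).
#' @param sr_window_ms Success window in ms (default 16).
#' @param dr_window_ms Detection window in ms (default 1000).
#' @return A list of class `gait_error_report` with elements `me_ms`,
#'   `mae_ms`, `iqr_ms`, `sd_ms`, `max_ms`, `sr_pct`, `dr_pct`, `n_events`.
#' @export
error_report <- function(matches, sr_window_ms = 16, dr_window_ms = 1000) {
  if (is.data.frame(matches)) matches <- list(matches)
  err <- unlist(lapply(matches, function(m) m$error_ms), use.names = FALSE)
  n <- length(err)
  if (n == 0L) stop("error_report requires at least one match", call. = FALSE)
  present <- err[!is.na(err)]
  succ <- present[abs(present) <= sr_window_ms]
  rep_ <- list(
    me_ms  = if (length(present)) mean(present) else NA_real_,
    mae_ms = if (length(present)) stats::median(abs(present)) else NA_real_,
    iqr_ms = if (length(present)) stats::IQR(present) else NA_real_,
    sd_ms  = if (length(succ) >= 2L) stats::sd(succ) else NA_real_,
    max_ms = if (length(present)) max(abs(present)) else NA_real_,
    sr_pct = 100 * length(succ) / n,
    dr_pct = 100 * sum(abs(present) <= dr_window_ms) / n,
    n_events = n
  )
  structure(rep_, class = "gait_error_report")
}

#' @export
print.gait_error_report <- function(x, ...) {
  cat(sprintf(paste0("<gait_error_report> n = %d\n",
                     "  ME %.3f ms | MAE %.3f ms | IQR %.3f ms | SD %.3f ms | MAX %.3f ms\n",
                     "  SR %.3f %% | DR %.3f %%\n"),
              x$n_events, x$me_ms, x$mae_ms, x$iqr_ms,
              ifelse(is.na(x$sd_ms), NaN, x$sd_ms), x$max_ms,
              x$sr_pct, x$dr_pct))
  invisible(x)
}

#' Serialize one or more error reports to CSV
#'
#' Columns follow the conventional reporting order: ME, MAE, IQR, SD, MAX,
#' SR, DR (plus the pooled event count and, when supplied, extra events).
#'
#' @param reports A named list of `gait_error_report`s (names become the
#'   `stream` column) or a single report.
#' @param path Output CSV path.
#' @param extra_events Optional integer vector aligned with `reports`.
#' @return Invisibly, `path`.
#' @export
write_error_report <- function(reports, path, extra_events = NULL) {
  if (inherits(reports, "gait_error_report")) reports <- list(all = reports)
  df <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(stream = nm, me_ms = r$me_ms, mae_ms = r$mae_ms,
               iqr_ms = r$iqr_ms, sd_ms = r$sd_ms, max_ms = r$max_ms,
               sr_pct = r$sr_pct, dr_pct = r$dr_pct, n_events = r$n_events)
  }))
  if (!is.null(extra_events)) df$extra_events <- extra_events
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Count extra (or missed) detected events
#'
#' Trims the detected stream to the span from the detected event closest to
#' the first reference event through the one closest to the last, then
#' returns `detected count - reference count`: positive values are extra
#' detections, negative values are misses.
#'
#' @param model,manual Event times (ms) for one stream, or [gait_events()]
#'   sets with `side`/`type` selecting the stream.
#' @param side,type Stream selector when event sets are given.
#' @return Signed integer.
#' @export
count_extra_events <- function(model, manual, side = "L", type = "HS") {
  mt <- if (inherits(model, "gait_events")) event_stream(model, side, type) else sort(as.numeric(model))
  rt <- if (inherits(manual, "gait_events")) event_stream(manual, side, type) else sort(as.numeric(manual))
  if (!length(rt)) stop("count_extra_events requires a non-empty reference stream",
                        call. = FALSE)
  if (!length(mt)) return(-length(rt))
  i1 <- which.min(abs(mt - rt[1]))
  i2 <- which.min(abs(mt - rt[length(rt)]))
  (i2 - i1 + 1L) - length(rt)
}
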