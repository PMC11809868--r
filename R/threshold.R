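#' Conventional GRF-threshold event detection
#'
#' The baseline detector: a heel strike is recorded at each upward crossing
#' of a force threshold set to a fraction of body weight (default 1%), and
#' a toe off at each downward crossing.  Entry uses `>=`, exit uses `<`, so
#' exact-threshold samples resolve deterministically.  No debouncing is
#' applied by default, which deliberately reproduces this method's failure
#' mode on foot-drag and cross-plate artifacts: any blip through the
#' threshold yields an extra HS/TO pair.
#'
#' @param grf A [gait_channel()] of kind `"grf_vertical"`.
#' @param body_weight_N Subject body weight in newtons.
#' @param threshold_fraction Threshold as a fraction of body weight
#'   (default 0.01).
#' @param side Side label attached to the returned events.
#' @param min_contact_ms Optional debounce: contacts (HS..TO) shorter than
#'   this are discarded together with their events.  Default 0 (off).
#' @return A [gait_events()] set with source `"threshold"`; HS and TO
#'   strictly alternate, starting with whichever crossing occurs first.
#' @export
detect_threshold_events <- function(grf, body_weight_N, threshold_fraction = 0.01,
                                    side = "L", min_contact_ms = 0) {
  stopifnot(inherits(grf, "gait_channel"))
  if (grf$kind != "grf_vertical")
    stop("detect_threshold_events requires a grf_vertical channel", call. = FALSE)
  if (!is.numeric(body_weight_N) || body_weight_N <= 0)
    stop("body_weight_N must be positive", call. = FALSE)
  thr <- threshold_fraction * body_weight_N
  above <- grf$values >= thr
  n <- length(above)
  # transitions between sample i-1 and i; event time is sample i
  up <- which(above[-1] & !above[-n]) + 1L
  down <- which(!above[-1] & above[-n]) + 1L
  t_ms <- (seq_len(n) - 1) / grf$rate_hz * 1000

  hs <- t_ms[up]; to <- t_ms[down]
  if (min_contact_ms > 0 && length(hs) && length(to)) {
    keep_hs <- rep(TRUE, length(hs)); keep_to <- rep(TRUE, length(to))
    for (i in seq_along(hs)) {
      j <- which(to > hs[i])[1]
      if (!is.na(j) && to[j] - hs[i] < min_contact_ms) {
        keep_hs[i] <- FALSE; keep_to[j] <- FALSE
      }
    }
    hs <- hs[keep_hs]; to <- to[keep_to]
  }
  gait_events(rep(side, length(hs) + length(to)),
              c(rep("HS", length(hs)), rep("TO", length(to))),
              c(hs, to), source = "threshold")
}
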