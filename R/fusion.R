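#' Fusion weights for combining per-signal confidence curves
#'
#' The exponents applied to the ipsilateral-GRF, contralateral-GRF, and
#' ipsilateral-heel model curves when they are multiplied into the final
#' confidence curve.  All exponents lie in \[0, 3\]; the shipped defaults
#' (a = 0.3, b = 0, c = 0.01) are the optimum found by event-RMSE tuning.
#'
#' @param a Exponent of the ipsilateral GRF curve.
#' @param b Exponent of the contralateral GRF curve (0 drops the term).
#' @param c Exponent of the ipsilateral heel curve.
#' @return An object of class `fusion_weights`.
#' @export
fusion_weights <- function(a = 0.3, b = 0, c = 0.01) {
  w <- c(a = a, b = b, c = c)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 3))
    stop("fusion exponents must lie in [0, 3]", call. = FALSE)
  structure(as.list(w), class = "fusion_weights")
}

#' @export
print.fusion_weights <- function(x, ...) {
  cat(sprintf("<fusion_weights> a = %g, b = %g, c = %g\n", x$a, x$b, x$c))
  invisible(x)
}

#' Signed power
#'
#' `sign(x) * |x|^p`, real-valued for fractional exponents applied to
#' negative model outputs.  By convention `p = 0` yields the constant 1
#' for every input (a zero-weighted curve drops out of the product
#' entirely).
#'
#' @param x Numeric vector.
#' @param p Non-negative exponent (scalar).
#' @return Numeric vector of the same length as `x`.
#' @export
signed_power <- function(x, p) {
  if (!is.numeric(p) || length(p) != 1L || p < 0)
    stop("p must be a single non-negative number", call. = FALSE)
  if (p == 0) return(rep(1, length(x)))
  sign(x) * abs(x)^p
}

#' Combine per-signal confidence curves into the final curve
#'
#' Multiplies the signed powers of the individual model outputs:
#' `C = sp(C_iGRF, a) * sp(C_cGRF, b) * sp(C_iHeel, c)`, where `sp` is
#' [signed_power()].  With `b = 0` (the shipped default) the contralateral
#' term is the constant 1 and `c_cgrf` may be omitted.
#'
#' @param c_igrf,c_iheel [gait_curve()]s of equal length (same stream).
#' @param weights A [fusion_weights()] object.
#' @param c_cgrf Optional contralateral-GRF curve; required when
#'   `weights$b > 0`.
#' @return A fused [gait_curve()] for the same stream as `c_igrf`.
#' @export
combine_curves <- function(c_igrf, c_iheel, weights = fusion_weights(),
                           c_cgrf = NULL) {
  stopifnot(inherits(c_igrf, "gait_curve"), inherits(c_iheel, "gait_curve"),
            inherits(weights, "fusion_weights"))
  if (length(c_igrf$values) != length(c_iheel$values))
    stop("curves must have equal length", call. = FALSE)
  if (weights$b > 0 && is.null(c_cgrf))
    stop("weights$b > 0 requires the contralateral GRF curve", call. = FALSE)
  v <- signed_power(c_igrf$values, weights$a) *
    signed_power(c_iheel$values, weights$c)
  if (!is.null(c_cgrf)) {
    if (length(c_cgrf$values) != length(c_igrf$values))
      stop("curves must have equal length", call. = FALSE)
    v <- v * signed_power(c_cgrf$values, weights$b)
  }
  gait_curve(v, c_igrf$rate_hz, c_igrf$side, c_igrf$type, c_igrf$sigma_ms)
}

#' Default exponent grid for fusion-weight tuning
#'
#' Log-spaced coverage of the admissible range \[0, 3\] that contains the
#' shipped optimum exactly.
#'
#' @return Numeric vector of candidate exponent values.
#' @export
fusion_weight_grid <- function() c(0, 0.01, 0.03, 0.1, 0.3, 1, 3)

#' Tune fusion weights by event RMSE
#'
#' Scores every candidate weight set by fusing the per-trial model curves,
#' decoding events, matching them to the reference events, and computing
#' the RMSE of the timing errors; a reference event with no detected event
#' within `penalty_ms` contributes `penalty_ms` (bounding the otherwise
#' undefined error of a miss by the matching horizon).  Ties keep the first
#' candidate in order.
#'
#' @param candidates List of [fusion_weights()] objects (>= 1).
#' @param curves_by_trial List (one element per trial) of per-stream model
#'   curves: each trial is a named list with one entry per stream name
#'   (`"L_HS"`, `"L_TO"`, `"R_HS"`, `"R_TO"`; any subset), each entry a
#'   list with elements `igrf`, `iheel`, and optionally `cgrf`.
#' @param reference List of [gait_events()] sets, one per trial.
#' @param min_height,min_interval_ms Peak-decoding parameters.
#' @param penalty_ms Penalty for unmatched reference events (default 1000).
#' @return A list with `best` (the argmin `fusion_weights`) and `table`
#'   (data frame `a, b, c, rmse_ms` in candidate order).
#' @export
tune_weights <- function(candidates, curves_by_trial, reference,
                         min_height = 0.3, min_interval_ms = 1000,
                         penalty_ms = 1000) {
  if (!length(candidates)) stop("need at least one candidate", call. = FALSE)
  stopifnot(length(curves_by_trial) == length(reference))
  score_one <- function(w) {
    sq <- numeric(0)
    for (i in seq_along(curves_by_trial)) {
      trial_curves <- curves_by_trial[[i]]
      ref <- reference[[i]]
      for (stream in names(trial_curves)) {
        cs <- trial_curves[[stream]]
        fused <- combine_curves(cs$igrf, cs$iheel, w, cs$cgrf)
        det <- decode_peaks(fused, min_height, min_interval_ms)
        side <- sub("_.*$", "", stream); type <- sub("^.*_", "", stream)
        m <- match_events(det, ref, side = side, type = type)
        e <- ifelse(is.na(m$error_ms) | abs(m$error_ms) > penalty_ms,
                    penalty_ms, m$error_ms)
        sq <- c(sq, e^2)
      }
    }
    if (!length(sq)) stop("no reference events to score against", call. = FALSE)
    sqrt(mean(sq))
  }
  rmse <- vapply(candidates, score_one, numeric(1))
  tab <- data.frame(a = vapply(candidates, `[[`, numeric(1), "a"),
                    b = vapply(candidates, `[[`, numeric(1), "b"),
                    c = vapply(candidates, `[[`, numeric(1), "c"),
                    rmse_ms = rmse)
  list(best = candidates[[which.min(rmse)]], table = tab)
}
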