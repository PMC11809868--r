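#' Build incremental training sequences from labeled trials
#'
#' Produces [training_sequence()]s in the incremental order used for
#' training: for each trial in the given order (cleanest first), the left
#' side then the right side.  Inputs are normalized with
#' [normalize_input()]; targets are Gaussian confidence curves encoded from
#' the labeled events.
#'
#' @param trials List of [gait_trial()]s (all channels on a common rate).
#' @param labels List of [gait_events()] sets aligned with `trials`.
#' @param input_kind `"igrf"`, `"cgrf"`, or `"iheel"`.
#' @param sigma_ms Gaussian width of the target curves (default 53.3 ms).
#' @return List of `training_sequence`s.
#' @export
build_training_sequences <- function(trials, labels, input_kind = "igrf",
                                     sigma_ms = 53.3) {
  stopifnot(length(trials) == length(labels))
  seqs <- list()
  for (i in seq_along(trials)) {
    trial <- trials[[i]]
    for (side in c("L", "R")) {
      ch <- trial_input_channel(trial, side, input_kind)
      input <- normalize_input(ch, trial$body_weight_N)
      n <- length(input$values)
      hs <- encode_events(labels[[i]], n, input$rate_hz, sigma_ms, side, "HS")
      to <- encode_events(labels[[i]], n, input$rate_hz, sigma_ms, side, "TO")
      seqs[[length(seqs) + 1L]] <-
        training_sequence(input, hs, to,
                          label = sprintf("%s_%s", trial$trial_id, side))
    }
  }
  seqs
}

# Channel feeding a model of the given input kind, for events on `side`.
trial_input_channel <- function(trial, side, input_kind) {
  other <- if (side == "L") "R" else "L"
  key <- switch(input_kind,
                igrf = sprintf("grf_%s", if (side == "L") "left" else "right"),
                cgrf = sprintf("grf_%s", if (other == "L") "left" else "right"),
                iheel = sprintf("heel_%s", if (side == "L") "left" else "right"),
                stop("unknown input_kind", call. = FALSE))
  trial$channels[[key]]
}

#' Detect gait events with the fused LSTM detector
#'
#' For each side, runs every per-signal model over that side's ipsilateral
#' channels, fuses the predicted HS and TO confidence curves with the
#' signed-power weighting, and decodes events by constrained peak
#' detection.
#'
#' @param models Named list of `lstm_model`s; requires `igrf` and `iheel`,
#'   plus `cgrf` when `weights$b > 0`.
#' @param trial A [gait_trial()] on a common rate.
#' @param weights A [fusion_weights()] (default the shipped optimum).
#' @param min_height,min_interval_ms Peak-decoding parameters.
#' @return A [gait_events()] set (source `"model"`) covering both sides
#'   and both event types.
#' @export
detect_events_fused <- function(models, trial, weights = fusion_weights(),
                                min_height = 0.3, min_interval_ms = 1000) {
  stopifnot(inherits(trial, "gait_trial"))
  if (is.null(models$igrf) || is.null(models$iheel))
    stop("models must contain at least 'igrf' and 'iheel'", call. = FALSE)
  if (weights$b > 0 && is.null(models$cgrf))
    stop("weights$b > 0 requires a 'cgrf' model", call. = FALSE)
  out <- NULL
  for (side in c("L", "R")) {
    curves <- lapply(models, function(m) {
      ch <- trial_input_channel(trial, side, m$config$input_kind)
      predict_curves(m, normalize_input(ch, trial$body_weight_N), side = side)
    })
    for (ty in c("hs", "to")) {
      fused <- combine_curves(curves$igrf[[ty]], curves$iheel[[ty]], weights,
                              if (!is.null(curves$cgrf)) curves$cgrf[[ty]])
      det <- decode_peaks(fused, min_height, min_interval_ms)
      out <- if (is.null(out)) det else
        gait_events(c(out$side, det$side), c(out$type, det$type),
                    c(out$time_ms, det$time_ms), source = "model")
    }
  }
  out
}

#' Scaled-down end-to-end detection benchmark
#'
#' The package's reference experiment at desk scale: simulate `n_trials`
#' three-minute trials at 100 Hz with foot-drag and cross-plate artifact
#' rates of 0.05, train the ipsilateral-GRF and heel models incrementally
#' (left/right alternating) on the first `n_train` trials using their truth
#' schedules as labels, fuse with the shipped weights (0.3, 0, 0.01),
#' decode with minimum peak height 0.3 and minimum interval 1000 ms, and
#' evaluate on the held-out trials against ground truth, pooling heel
#' strikes and toe offs over both sides.
#'
#' @param seed Base seed; trial `i` is simulated with seed `seed + i - 1`,
#'   and model training uses `seed` (GRF model) and `seed + 1` (heel
#'   model).
#' @param n_trials,n_train Number of simulated and training trials.
#' @param duration_s,rate_hz,drag_rate,cross_plate_rate Simulator settings.
#' @param weights Fusion weights (default [fusion_weights()]).
#' @param verbose Print progress to stderr.
#' @return A list with `report` (pooled [error_report()]), `sr_pct`,
#'   `dr_pct`, `me_ms`, `n_events`, the trained `models`, and the
#'   per-stream `matches`.
#' @export
run_desk_benchmark <- function(seed = 1L, n_trials = 40L, n_train = 2L,
                               duration_s = 180, rate_hz = 100,
                               drag_rate = 0.05, cross_plate_rate = 0.05,
                               weights = fusion_weights(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  sims <- lapply(seq_len(n_trials), function(i)
    simulate_trial(sim_params(duration_s = duration_s, rate_hz = rate_hz,
                              drag_rate = drag_rate,
                              cross_plate_rate = cross_plate_rate,
                              seed = seed + i - 1L)))
  trials <- lapply(sims, `[[`, "trial")
  truths <- lapply(sims, `[[`, "truth")
  say("simulated %d trials (%g s at %g Hz)", n_trials, duration_s, rate_hz)

  train_trials <- trials[seq_len(n_train)]
  train_truths <- truths[seq_len(n_train)]
  models <- list()
  for (kind in c("igrf", "iheel")) {
    cfg <- lstm_config("desk", input_kind = kind,
                       seed = seed + match(kind, c("igrf", "iheel")) - 1L)
    seqs <- build_training_sequences(train_trials, train_truths, kind)
    say("training %s model (%d increments x %d epochs)...",
        kind, length(seqs), cfg$epochs_per_increment)
    models[[kind]] <- train_incremental(cfg, seqs)
  }

  matches <- list()
  test_idx <- setdiff(seq_len(n_trials), seq_len(n_train))
  for (i in test_idx) {
    det <- detect_events_fused(models, trials[[i]], weights)
    for (side in c("L", "R")) for (ty in c("HS", "TO"))
      matches[[sprintf("trial%d_%s_%s", i, side, ty)]] <-
        match_events(det, truths[[i]], side = side, type = ty)
    say("evaluated trial %d/%d", i, n_trials)
  }
  report <- error_report(matches)
  list(report = report, sr_pct = report$sr_pct, dr_pct = report$dr_pct,
       me_ms = report$me_ms, n_events = report$n_events,
       models = models, matches = matches)
}
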