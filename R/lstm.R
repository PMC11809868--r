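#' LSTM detector configuration
#'
#' Hyperparameters of a single-signal sequence-to-sequence LSTM event
#' detector.  The `"full"` preset is the full-scale configuration (540
#' hidden units, minibatch 110, 500 epochs per increment, 2000-sample
#' chunks at 1000 Hz); the `"desk"` preset is a scaled-down configuration
#' for CPU-scale work (64 hidden units, minibatch 16, 100 epochs per
#' increment, 400-sample chunks at 100 Hz).
#'
#' @param preset `"desk"` or `"full"`.
#' @param input_kind Which channel the model consumes: `"igrf"`
#'   (ipsilateral vertical GRF), `"cgrf"` (contralateral GRF), or `"iheel"`
#'   (ipsilateral heel height).
#' @param hidden_units,minibatch,epochs_per_increment,chunk_length_samples,chunk_overlap_samples
#'   Override individual preset values.
#' @param initial_learning_rate Adam initial learning rate (default 1e-2).
#' @param decay_factor Multiplicative learning-rate decay (default 0.5).
#' @param decay_every_epochs Epochs between decays within an increment
#'   (default 50).
#' @param grad_clip Global L2 gradient-norm clip (default 5; 0 disables).
#' @param seed Integer seed governing weight initialization and minibatch
#'   shuffling.
#' @return A list of class `lstm_config`.
#' @export
lstm_config <- function(preset = c("desk", "full"),
                        input_kind = c("igrf", "cgrf", "iheel"),
                        hidden_units = NULL, minibatch = NULL,
                        epochs_per_increment = NULL,
                        chunk_length_samples = NULL,
                        chunk_overlap_samples = NULL,
                        initial_learning_rate = 1e-2, decay_factor = 0.5,
                        decay_every_epochs = 50L, grad_clip = 5,
                        seed = 1L) {
  preset <- match.arg(preset)
  input_kind <- match.arg(input_kind)
  defaults <- switch(preset,
    full = list(hidden_units = 540L, minibatch = 110L,
                 epochs_per_increment = 500L, chunk_length_samples = 2000L,
                 chunk_overlap_samples = 200L),
    desk = list(hidden_units = 64L, minibatch = 16L,
                epochs_per_increment = 100L, chunk_length_samples = 400L,
                chunk_overlap_samples = 40L))
  pick <- function(x, d) if (is.null(x)) d else as.integer(x)
  cfg <- list(
    preset = preset, input_kind = input_kind,
    hidden_units = pick(hidden_units, defaults$hidden_units),
    minibatch = pick(minibatch, defaults$minibatch),
    epochs_per_increment = pick(epochs_per_increment, defaults$epochs_per_increment),
    chunk_length_samples = pick(chunk_length_samples, defaults$chunk_length_samples),
    chunk_overlap_samples = pick(chunk_overlap_samples, defaults$chunk_overlap_samples),
    initial_learning_rate = initial_learning_rate,
    decay_factor = decay_factor,
    decay_every_epochs = as.integer(decay_every_epochs),
    grad_clip = grad_clip,
    seed = as.integer(seed))
  if (cfg$hidden_units < 1L) stop("hidden_units must be >= 1", call. = FALSE)
  if (cfg$chunk_length_samples < 2L) stop("chunk_length_samples must be >= 2", call. = FALSE)
  if (cfg$minibatch < 1L || cfg$epochs_per_increment < 1L || cfg$decay_every_epochs < 1L)
    stop("minibatch, epochs and decay interval must be >= 1", call. = FALSE)
  if (cfg$initial_learning_rate <= 0) stop("initial_learning_rate must be > 0", call. = FALSE)
  if (cfg$decay_factor <= 0 || cfg$decay_factor > 1)
    stop("decay_factor must lie in (0, 1]", call. = FALSE)
  structure(cfg, class = "lstm_config")
}

#' Learning rate at a given epoch of an increment
#'
#' The schedule halves the rate every `decay_every_epochs` epochs (by
#' default 50% every 50 epochs) and restarts with each training increment:
#' `initial * decay_factor^floor(epoch / decay_every_epochs)` with `epoch`
#' counted from 0.
#'
#' @param config An [lstm_config()].
#' @param epoch 0-based epoch index within an increment.
#' @return Learning rate.
#' @export
learning_rate_at <- function(config, epoch) {
  stopifnot(inherits(config, "lstm_config"), all(epoch >= 0))
  config$initial_learning_rate *
    config$decay_factor^(floor(epoch / config$decay_every_epochs))
}

#' Normalize an input channel for the LSTM
#'
#' GRF channels are expressed in units of body weight; heel-height channels
#' are min-max scaled to \[0, 1\] per trial (a constant heel channel maps
#' to all zeros).
#'
#' @param channel A [gait_channel()].
#' @param body_weight_N Body weight in newtons (used for GRF channels).
#' @return A `gait_channel` with normalized values.
#' @export
normalize_input <- function(channel, body_weight_N) {
  stopifnot(inherits(channel, "gait_channel"))
  if (channel$kind == "grf_vertical") {
    if (!is.numeric(body_weight_N) || body_weight_N <= 0)
      stop("body_weight_N must be positive", call. = FALSE)
    v <- channel$values / body_weight_N
  } else {
    rng <- range(channel$values)
    v <- if (diff(rng) == 0) rep(0, length(channel$values))
         else (channel$values - rng[1]) / diff(rng)
  }
  gait_channel(v, channel$rate_hz, channel$kind)
}

#' Bundle one training sequence
#'
#' One side of one trial: a normalized input channel plus its target HS and
#' TO confidence curves (equal lengths).
#'
#' @param input Normalized [gait_channel()].
#' @param target_hs,target_to [gait_curve()]s of the same length as `input`.
#' @param label Ordering key, e.g. `"trial1_L"`.
#' @return A list of class `training_sequence`.
#' @export
training_sequence <- function(input, target_hs, target_to, label = "") {
  stopifnot(inherits(input, "gait_channel"),
            inherits(target_hs, "gait_curve"), inherits(target_to, "gait_curve"))
  if (length(input$values) != length(target_hs$values) ||
      length(input$values) != length(target_to$values))
    stop("input and target lengths must agree", call. = FALSE)
  structure(list(input = input, target_hs = target_hs, target_to = target_to,
                 label = as.character(label)),
            class = "training_sequence")
}

init_weights <- function(hidden_units) {
  h <- hidden_units
  s <- 1 / sqrt(h)
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -s, s), nr, nc)
  b <- rep(0, 4 * h)
  b[(h + 1):(2 * h)] <- 1  # forget-gate bias starts open
  list(Wx = u(4 * h, 1), Wh = u(4 * h, h), b = b, Wy = u(2, h), by = rep(0, 2))
}

zero_like <- function(w) lapply(w, function(x) x * 0)

# Training chunks start every len/2 samples (50% overlap), so each sample
# is seen both warm and cold and the optimizer takes twice as many steps
# per epoch; any tail shorter than one chunk is dropped.
chunk_matrix <- function(v, len) {
  if (length(v) < len)
    stop(sprintf("sequence shorter than one chunk (%d samples)", len), call. = FALSE)
  stride <- max(1L, len %/% 2L)
  starts <- seq(1L, length(v) - len + 1L, by = stride)
  vapply(starts, function(s) v[s:(s + len - 1L)], numeric(len))
}

#' Train an LSTM detector incrementally
#'
#' Trains the single-layer LSTM (one input feature, linear head to the HS
#' and TO confidence outputs, MSE loss, Adam) on each sequence in turn,
#' continuing from the current weights -- the incremental schedule in which
#' the left side of the cleanest trial is used first, then its right side,
#' then the next trial's sides, and so on.  Within each increment the
#' learning-rate schedule and the Adam state restart; sequences are split
#' into fixed-length chunks which are shuffled each epoch and taken
#' `minibatch` at a time.  Fixing `config$seed` makes the result
#' bit-reproducible.
#'
#' @param config An [lstm_config()].
#' @param sequences Ordered list of [training_sequence()]s.
#' @return An object of class `lstm_model`: weights, config, and the
#'   per-increment loss history.
#' @export
train_incremental <- function(config, sequences) {
  stopifnot(inherits(config, "lstm_config"))
  if (!length(sequences)) stop("need at least one training sequence", call. = FALSE)
  for (s in sequences)
    if (!inherits(s, "training_sequence"))
      stop("sequences must be training_sequence objects", call. = FALSE)

  with_local_seed(config$seed, {
    w <- init_weights(config$hidden_units)
    history <- vector("list", length(sequences))
    for (k in seq_along(sequences)) {
      sq <- sequences[[k]]
      x <- chunk_matrix(sq$input$values, config$chunk_length_samples)
      yh <- chunk_matrix(sq$target_hs$values, config$chunk_length_samples)
      yt <- chunk_matrix(sq$target_to$values, config$chunk_length_samples)
      n_chunks <- ncol(x)
      order_mat <- t(vapply(seq_len(config$epochs_per_increment),
                            function(e) sample.int(n_chunks),
                            integer(n_chunks)))
      adam <- list(m = zero_like(w), v = zero_like(w), t = 0L)
      fit <- .lstm_train(w, x, yh, yt, order_mat, config$minibatch,
                         config$initial_learning_rate, config$decay_factor,
                         config$decay_every_epochs, adam, config$grad_clip)
      w <- fit$weights
      history[[k]] <- fit$loss
      names(history)[k] <- if (nzchar(sq$label)) sq$label else sprintf("increment%d", k)
    }
    structure(list(weights = w, config = config, loss_history = history,
                   rate_hz = sequences[[1]]$input$rate_hz,
                   sigma_ms = sequences[[1]]$target_hs$sigma_ms),
              class = "lstm_model")
  })
}

#' @export
print.lstm_model <- function(x, ...) {
  final <- vapply(x$loss_history, function(l) l[length(l)], numeric(1))
  cat(sprintf("<lstm_model> %s, %d hidden units, %d increment(s); final losses: %s\n",
              x$config$input_kind, x$config$hidden_units, length(x$loss_history),
              paste(sprintf("%.2e", final), collapse = ", ")))
  invisible(x)
}

# Forward pass over a T x B matrix of normalized inputs.
predict_matrix <- function(model, x) {
  .lstm_forward(model$weights, x)
}

#' Predict HS and TO confidence curves for one input channel
#'
#' Runs the trained network over the full sequence.  With `chunk_length`
#' set, the sequence is instead processed in chunks that each start
#' `chunk_overlap` samples early; the warm-up overlap is discarded when the
#' chunk outputs are stitched, so memory stays bounded on long records.
#'
#' @param model An `lstm_model` from [train_incremental()].
#' @param input Normalized [gait_channel()] (see [normalize_input()]).
#' @param side Side label for the returned curves.
#' @param chunk_length Optional chunk length in samples (NULL = whole
#'   sequence).
#' @param chunk_overlap Warm-up overlap in samples when chunking (defaults
#'   to the config's `chunk_overlap_samples`).
#' @return List with elements `hs` and `to`, both [gait_curve()]s of the
#'   input's length.
#' @export
predict_curves <- function(model, input, side = "L", chunk_length = NULL,
                           chunk_overlap = NULL) {
  stopifnot(inherits(model, "lstm_model"), inherits(input, "gait_channel"))
  v <- input$values
  if (!length(v)) stop("input channel is empty", call. = FALSE)
  if (is.null(chunk_length)) {
    out <- predict_matrix(model, matrix(v, ncol = 1))
    hs <- out$hs[, 1]; to <- out$to[, 1]
  } else {
    ov <- if (is.null(chunk_overlap)) model$config$chunk_overlap_samples else chunk_overlap
    n <- length(v)
    hs <- numeric(n); to <- numeric(n)
    start <- 1L
    while (start <= n) {
      stop_ <- min(start + chunk_length - 1L, n)
      from <- max(1L, start - ov)
      out <- predict_matrix(model, matrix(v[from:stop_], ncol = 1))
      keep <- (start - from + 1L):(stop_ - from + 1L)
      hs[start:stop_] <- out$hs[keep, 1]
      to[start:stop_] <- out$to[keep, 1]
      start <- stop_ + 1L
    }
  }
  list(hs = gait_curve(hs, input$rate_hz, side, "HS", model$sigma_ms),
       to = gait_curve(to, input$rate_hz, side, "TO", model$sigma_ms))
}

#' Save / load a trained detector
#'
#' Checkpoints store the weight matrices, the [lstm_config()], and the
#' curve metadata (rate, Gaussian width) in a single RDS container.
#'
#' @param model An `lstm_model`.
#' @param path File path.
#' @return `save_lstm_model()`: invisibly `path`;
#'   `load_lstm_model()`: the restored `lstm_model`.
#' @export
save_lstm_model <- function(model, path) {
  stopifnot(inherits(model, "lstm_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_lstm_model
#' @export
load_lstm_model <- function(path) {
  obj <- readRDS(path)
  class(obj$config) <- "lstm_config"
  structure(obj, class = "lstm_model")
}
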