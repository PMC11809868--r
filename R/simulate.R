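#' Simulation parameters for synthetic slow treadmill walking
#'
#' The simulator emulates slow treadmill walking on a split-belt
#' instrumented treadmill (belt speed ~0.49 m/s), with a double-hump
#' vertical GRF during stance, a raised-cosine heel-height arc during
#' swing, and the three strike conditions seen in exoskeleton experiments:
#' clean strikes, cross-plate (unclean) strikes that contaminate the
#' contralateral force plate, and foot drag producing a premature-contact
#' force blip mid-swing.
#'
#' @param duration_s Trial length in seconds (default 180, a typical
#'   three-minute trial).
#' @param rate_hz Sampling rate of all simulated channels (default 1000;
#'   the desk-scale presets use 100).
#' @param belt_speed_mps Nominal belt speed, m/s (metadata only).
#' @param stride_period_ms Nominal stride period (default 2000 ms, slow
#'   walking).
#' @param stride_jitter_ms SD of the per-stride period jitter (default 50).
#' @param stance_fraction Fraction of the stride spent in stance
#'   (default 0.65).
#' @param body_weight_N Body weight (default 700 N).
#' @param grf_peak_factor Height of the two GRF humps as a multiple of body
#'   weight (default 1.1).
#' @param heel_lift_mm Peak heel height during swing (default 150 mm).
#' @param noise_sd_N SD of additive Gaussian force-plate noise (default 1).
#' @param drag_rate Per-swing probability of a foot-drag blip (default 0).
#' @param cross_plate_rate Per-stance probability that part of the stance
#'   force lands on the contralateral plate (default 0).
#' @param seed Integer seed; every random draw flows from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(duration_s = 180, rate_hz = 1000, belt_speed_mps = 0.491,
                       stride_period_ms = 2000, stride_jitter_ms = 50,
                       stance_fraction = 0.65, body_weight_N = 700,
                       grf_peak_factor = 1.1, heel_lift_mm = 150,
                       noise_sd_N = 1, drag_rate = 0, cross_plate_rate = 0,
                       seed = 1L) {
  p <- list(duration_s = duration_s, rate_hz = rate_hz,
            belt_speed_mps = belt_speed_mps,
            stride_period_ms = stride_period_ms,
            stride_jitter_ms = stride_jitter_ms,
            stance_fraction = stance_fraction, body_weight_N = body_weight_N,
            grf_peak_factor = grf_peak_factor, heel_lift_mm = heel_lift_mm,
            noise_sd_N = noise_sd_N, drag_rate = drag_rate,
            cross_plate_rate = cross_plate_rate, seed = as.integer(seed))
  if (p$stance_fraction <= 0 || p$stance_fraction >= 1)
    stop("stance_fraction must lie in (0, 1)", call. = FALSE)
  if (p$rate_hz <= 0 || p$duration_s <= 0 || p$stride_period_ms <= 0)
    stop("rates, duration and stride period must be positive", call. = FALSE)
  if (p$drag_rate < 0 || p$drag_rate > 1 || p$cross_plate_rate < 0 || p$cross_plate_rate > 1)
    stop("artifact rates must be probabilities in [0, 1]", call. = FALSE)
  if (p$body_weight_N <= 0) stop("body_weight_N must be positive", call. = FALSE)
  if (p$stride_jitter_ms < 0 || p$noise_sd_N < 0)
    stop("jitter and noise SDs must be non-negative", call. = FALSE)
  structure(p, class = "sim_params")
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Event schedule at continuous resolution, before grid snapping.
schedule_continuous <- function(params) {
  per_nom <- params$stride_period_ms
  dur_ms <- params$duration_s * 1000
  t0 <- per_nom
  limit <- dur_ms - per_nom / 2
  hs_l <- numeric(0); per <- numeric(0)
  t <- t0
  repeat {
    p <- per_nom + stats::rnorm(1, 0, params$stride_jitter_ms)
    p <- min(max(p, 0.5 * per_nom), 1.5 * per_nom)
    if (t + p > limit) break
    hs_l <- c(hs_l, t); per <- c(per, p)
    t <- t + p
  }
  if (!length(hs_l))
    stop("trial too short for a single stride; increase duration_s", call. = FALSE)
  stance <- params$stance_fraction * per
  list(hs_l = hs_l, to_l = hs_l + stance,
       hs_r = hs_l + per / 2, to_r = hs_l + per / 2 + stance)
}

#' Ground-truth gait event schedule
#'
#' Left heel strikes fall at cumulative jittered stride periods (starting
#' one nominal period into the trial); each toe off follows its heel strike
#' by `stance_fraction` of that stride's period; the right side is offset
#' by half a period.  Event times are snapped to the simulation sample grid
#' (truth at sensor resolution, mirroring labels derived from sampled
#' signals).
#'
#' @param params A [sim_params()] object.
#' @return A [gait_events()] set with source `"truth"`.
#' @export
make_gait_schedule <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_local_seed(params$seed, {
    s <- schedule_continuous(params)
    snap <- function(t) round(t * params$rate_hz / 1000) / params$rate_hz * 1000
    n <- length(s$hs_l)
    gait_events(side = rep(c("L", "L", "R", "R"), each = n),
                type = rep(c("HS", "TO", "HS", "TO"), each = n),
                time_ms = snap(c(s$hs_l, s$to_l, s$hs_r, s$to_r)),
                source = "truth")
  })
}

#' Vertical GRF stance profile
#'
#' The canonical M-shaped (double-hump) vertical GRF as a function of
#' stance phase: zero at contact and toe off, maxima of
#' `grf_peak_factor * body_weight_N` at 22% and 78% of stance, and a
#' mid-stance valley of 0.75 body weight.  Loading and unloading ramps are
#' steep quarter-sine segments (full unloading in the last ~2% of stance),
#' matching the near-instantaneous loading rate of a real strike; between
#' the ramp ends the profile is a chain of cosine eases, so it is
#' continuously differentiable on (0, 1).
#'
#' @param phase Numeric vector of stance-phase values; values outside
#'   \[0, 1\] return 0.
#' @param params A [sim_params()] object (peak scaling and body weight).
#' @return Force in newtons, same length as `phase`.
#' @export
grf_stance_profile <- function(phase, params) {
  stopifnot(inherits(params, "sim_params"))
  peak <- params$grf_peak_factor * params$body_weight_N
  dip <- 0.75 * params$body_weight_N
  p_up <- 0.02; f_up <- 0.5 * peak
  ease <- function(p, pa, pb, fa, fb)
    fa + (fb - fa) * 0.5 * (1 - cos(pi * (p - pa) / (pb - pa)))
  f <- numeric(length(phase))
  p <- phase
  seg <- function(lo, hi) which(p >= lo & p < hi)
  i <- seg(0, p_up);        f[i] <- f_up * sin(pi * p[i] / (2 * p_up))
  i <- seg(p_up, 0.22);     f[i] <- ease(p[i], p_up, 0.22, f_up, peak)
  i <- seg(0.22, 0.5);      f[i] <- ease(p[i], 0.22, 0.5, peak, dip)
  i <- seg(0.5, 0.78);      f[i] <- ease(p[i], 0.5, 0.78, dip, peak)
  i <- seg(0.78, 1 - p_up); f[i] <- ease(p[i], 0.78, 1 - p_up, peak, f_up)
  i <- which(p >= 1 - p_up & p <= 1)
  f[i] <- f_up * sin(pi * (1 - p[i]) / (2 * p_up))
  f
}

# Raised-cosine heel arc over normalized swing time u in [0, 1]:
# rises to heel_lift_mm at u = 0.35 (shortly after toe off), then descends
# to 0 at the next heel strike.
heel_swing_arc <- function(u, heel_lift_mm) {
  h <- numeric(length(u))
  i <- which(u >= 0 & u < 0.35)
  h[i] <- heel_lift_mm * 0.5 * (1 - cos(pi * u[i] / 0.35))
  i <- which(u >= 0.35 & u <= 1)
  h[i] <- heel_lift_mm * 0.5 * (1 + cos(pi * (u[i] - 0.35) / 0.65))
  h
}

#' Simulate a complete walking trial
#'
#' Assembles the four trial channels from the ground-truth schedule:
#' stance-profile GRF per foot (the first stance sample already carries
#' load, so a 1%-body-weight threshold crossing lands exactly on the truth
#' heel strike, matching the labeling convention of threshold-initialized
#' events), heel-height arcs during swing, then -- in a fixed draw order
#' for reproducibility -- foot-drag blips (50-150 ms, 2-8% body weight,
#' mid-swing), cross-plate contamination (10-40% of a stance's force added
#' to the contralateral plate), and additive Gaussian sensor noise (GRF
#' clipped at 0).
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `trial` (a [gait_trial()]) and `truth`
#'   (a [gait_events()] set).
#' @export
simulate_trial <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_local_seed(params$seed, {
    sc <- schedule_continuous(params)
    rate <- params$rate_hz
    snap_ms <- function(t) round(t * rate / 1000) / rate * 1000
    n <- as.integer(round(params$duration_s * rate))
    t_ms <- (seq_len(n) - 1) / rate * 1000
    dt_ms <- 1000 / rate

    sides <- list(
      L = list(hs = snap_ms(sc$hs_l), to = snap_ms(sc$to_l)),
      R = list(hs = snap_ms(sc$hs_r), to = snap_ms(sc$to_r))
    )
    grf <- list(L = numeric(n), R = numeric(n))
    heel <- list(L = numeric(n), R = numeric(n))
    stance_force <- function(hs, to) {
      i <- which(t_ms >= hs & t_ms < to)
      # contact occurs just before the HS sample: offset phase by half a sample
      ph <- (t_ms[i] - hs + dt_ms / 2) / (to - hs)
      list(idx = i, f = grf_stance_profile(ph, params))
    }

    for (s in c("L", "R")) {
      ev <- sides[[s]]
      for (k in seq_along(ev$hs)) {
        st <- stance_force(ev$hs[k], ev$to[k])
        grf[[s]][st$idx] <- grf[[s]][st$idx] + st$f
      }
      # swing arcs between each TO and the following HS, plus a lead-in
      # descent before the first HS so the trial starts mid-swing
      swing_from <- c(max(0, ev$hs[1] - (1 - params$stance_fraction) * params$stride_period_ms),
                      ev$to)
      swing_to <- c(ev$hs, Inf)
      for (k in seq_along(swing_from)) {
        if (!is.finite(swing_to[k])) next
        i <- which(t_ms > swing_from[k] & t_ms < swing_to[k])
        if (!length(i)) next
        u <- (t_ms[i] - swing_from[k]) / (swing_to[k] - swing_from[k])
        heel[[s]][i] <- heel_swing_arc(u, params$heel_lift_mm)
      }
    }

    truth_all <- list(L = sides$L, R = sides$R)

    # foot-drag blips (draw order: L swings, then R swings)
    for (s in c("L", "R")) {
      ev <- sides[[s]]
      n_sw <- length(ev$to) - 1L
      if (n_sw < 1L || params$drag_rate == 0) {
        # keep the draw count independent of drag_rate only when rate is 0
        next
      }
      for (k in seq_len(n_sw)) {
        if (stats::runif(1) >= params$drag_rate) next
        sw0 <- ev$to[k]; sw1 <- ev$hs[k + 1L]
        center <- sw0 + stats::runif(1, 0.2, 0.8) * (sw1 - sw0)
        dur <- stats::runif(1, 50, 150)
        amp <- stats::runif(1, 0.02, 0.08) * params$body_weight_N
        i <- which(t_ms > center - dur / 2 & t_ms < center + dur / 2)
        if (length(i))
          grf[[s]][i] <- grf[[s]][i] +
            amp * 0.5 * (1 + cos(2 * pi * (t_ms[i] - center) / dur))
      }
    }

    # cross-plate contamination (L stances onto R plate, then R onto L)
    if (params$cross_plate_rate > 0) {
      for (s in c("L", "R")) {
        other <- if (s == "L") "R" else "L"
        ev <- sides[[s]]
        for (k in seq_along(ev$hs)) {
          if (stats::runif(1) >= params$cross_plate_rate) next
          frac <- stats::runif(1, 0.1, 0.4)
          st <- stance_force(ev$hs[k], ev$to[k])
          grf[[other]][st$idx] <- grf[[other]][st$idx] + frac * st$f
        }
      }
    }

    if (params$noise_sd_N > 0) {
      for (s in c("L", "R"))
        grf[[s]] <- pmax(grf[[s]] + stats::rnorm(n, 0, params$noise_sd_N), 0)
    }

    trial <- gait_trial(
      trial_id = sprintf("sim-%d", params$seed),
      body_weight_N = params$body_weight_N,
      grf_left = gait_channel(grf$L, rate, "grf_vertical"),
      grf_right = gait_channel(grf$R, rate, "grf_vertical"),
      heel_left = gait_channel(heel$L, rate, "heel_height"),
      heel_right = gait_channel(heel$R, rate, "heel_height"),
      condition = "no_exo"
    )
    nev <- length(truth_all$L$hs)
    truth <- gait_events(
      side = c(rep("L", 2L * nev), rep("R", 2L * nev)),
      type = rep(rep(c("HS", "TO"), each = nev), 2L),
      time_ms = c(truth_all$L$hs, truth_all$L$to, truth_all$R$hs, truth_all$R$to),
      source = "truth"
    )
    list(trial = trial, truth = truth)
  })
}
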