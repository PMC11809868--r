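test_that("the jitter-free schedule follows the stated arithmetic", {
  p <- sim_params(duration_s = 30, rate_hz = 1000, stride_jitter_ms = 0, seed = 1)
  sched <- make_gait_schedule(p)
  hs_l <- event_stream(sched, "L", "HS")
  to_l <- event_stream(sched, "L", "TO")
  hs_r <- event_stream(sched, "R", "HS")
  k <- seq_along(hs_l)
  expect_equal(hs_l, k * 2000)                    # cumulative periods
  expect_equal(to_l, k * 2000 + 1300)             # + stance fraction
  expect_equal(hs_r, k * 2000 + 1000)             # half-period offset
  expect_lt(max(sched$time_ms), 30000)
  expect_identical(make_gait_schedule(p), sched)  # fixed seed: identical
})

test_that("a known duration yields the requested number of strides", {
  # strides fit while HS + period <= duration - period/2; with the first HS
  # one period in, 24 s holds exactly 10 jitter-free strides per side
  p <- sim_params(duration_s = 24, rate_hz = 100, stride_jitter_ms = 0, seed = 1)
  sim <- simulate_trial(p)
  for (s in c("L", "R")) for (ty in c("HS", "TO"))
    expect_equal(length(event_stream(sim$truth, s, ty)), 10L)
})

test_that("the stance profile is an M-shape hitting its stated landmarks", {
  p <- sim_params(seed = 1)
  expect_identical(grf_stance_profile(0, p), 0)
  expect_identical(grf_stance_profile(1, p), 0)
  expect_identical(grf_stance_profile(c(-0.1, 1.1), p), c(0, 0))
  grid <- seq(0, 1, by = 1e-4)
  f <- grf_stance_profile(grid, p)
  expect_equal(max(f), 1.1 * 700, tolerance = 0.01)      # peaks near 22/78%
  at <- function(p0) f[which.min(abs(grid - p0))]
  expect_equal(at(0.5), 0.75 * 700, tolerance = 1e-6)    # mid-stance dip
  expect_equal(at(0.22), 1.1 * 700, tolerance = 1e-6)
  expect_equal(at(0.78), 1.1 * 700, tolerance = 1e-6)
  expect_lt(max(abs(diff(f))) * 1e4, 60 * 700)   # no jumps: bounded slope
})

test_that("simulated trials are reproducible and physically sane", {
  p <- quick_params(seed = 17L, drag_rate = 0.2, cross_plate_rate = 0.2,
                    noise_sd_N = 2)
  a <- simulate_trial(p)
  b <- simulate_trial(p)
  expect_identical(a, b)

  grf <- a$trial$channels$grf_left$values
  expect_true(all(grf >= 0))

  clean <- simulate_trial(clean_params(seed = 18L))
  v <- clean$trial$channels$grf_right$values
  t_ms <- channel_times_ms(clean$trial$channels$grf_right)
  hs <- event_stream(clean$truth, "R", "HS")
  to <- event_stream(clean$truth, "R", "TO")
  in_stance <- rep(FALSE, length(v))
  for (k in seq_along(hs)) in_stance[t_ms >= hs[k] & t_ms < to[k]] <- TRUE
  expect_true(all(v[!in_stance] < 0.01 * 700))   # clean swing stays below 1% BW

  heel <- clean$trial$channels$heel_right$values
  expect_true(all(heel >= 0))
  expect_true(all(heel[in_stance] == 0))         # heel flat on the ground
  # per-stride heel maximum falls strictly between TO and the next HS
  for (k in seq_len(length(to) - 1L)) {
    i <- which(t_ms > to[k] & t_ms < hs[k + 1L])
    peak_t <- t_ms[i][which.max(heel[i])]
    expect_gt(peak_t, to[k])
    expect_lt(peak_t, hs[k + 1L])
    expect_gt(max(heel[i]), 100)
  }
})

test_that("baseline extra events grow with the drag rate", {
  rates <- c(0, 0.1, 0.3, 0.6)
  extras <- vapply(rates, function(r) {
    total <- 0
    for (seed in 1:3) {
      sim <- simulate_trial(quick_params(seed = seed, drag_rate = r))
      det <- detect_threshold_events(sim$trial$channels$grf_left, 700)
      total <- total + count_extra_events(det, sim$truth, "L", "HS")
    }
    total
  }, numeric(1))
  expect_true(all(diff(extras) >= 0))
  expect_gt(extras[4], extras[1])
})

test_that("realized stride periods agree with the nominal mean", {
  p <- sim_params(duration_s = 150, rate_hz = 100, seed = 23)  # ~70 strides
  hs <- event_stream(make_gait_schedule(p), "L", "HS")
  per <- diff(hs)
  expect_gte(length(per), 50)
  se <- stats::sd(per) / sqrt(length(per))
  expect_lt(abs(mean(per) - 2000), 2 * se + 1e-9)
})
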