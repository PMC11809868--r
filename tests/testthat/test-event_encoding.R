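test_that("encoder places unit Gaussians with sigma 53.3 ms and zero floor", {
  ev <- gait_events("L", "HS", 5000, source = "manual")
  curve <- encode_events(ev, n_samples = 10000, rate_hz = 1000)
  t_ms <- (seq_len(10000) - 1)

  expect_identical(curve$values[t_ms == 5000], 1)                   # peak of 1
  expect_equal(curve$values[t_ms == 5053],                          # one sigma out
               exp(-53^2 / (2 * 53.3^2)), tolerance = 1e-12)
  expect_identical(curve$values[t_ms == 5300], 0)                   # 300 ms away: 0
  expect_true(all(curve$values >= 0 & curve$values <= 1))
  expect_equal(which.max(curve$values), 5001L)
})

test_that("encoder rejects events outside the window and overlaps take the max", {
  ev <- gait_events("L", "HS", 12000, source = "manual")
  expect_error(encode_events(ev, 10000, 1000), "outside")

  near <- gait_events(c("L", "L"), c("HS", "HS"), c(5000, 5060), source = "manual")
  curve <- encode_events(near, 10000, 1000)
  expect_equal(max(curve$values), 1)   # overlap must not sum above 1
  expect_identical(curve$values[5001], 1)
  expect_identical(curve$values[5061], 1)
})

test_that("decode obeys the height threshold and reports plateau centers", {
  low <- bump_curve(3000, 0.2, 1000)
  expect_equal(nrow(decode_peaks(low)), 0L)

  one <- bump_curve(5000, 1, 1000)
  expect_equal(decode_peaks(one)$time_ms, 5000)

  flat <- gait_curve(c(rep(0, 10), rep(0.9, 5), rep(0, 10)), 100)
  expect_equal(decode_peaks(flat)$time_ms, (13 - 1) / 100 * 1000)  # center of run 11..15
})

test_that("greedy decode matches the brute-force admissible-subset oracle", {
  # worked case: 0.9 @ 3000 suppresses 0.8 @ 3500 within the 1000 ms interval
  two <- bump_curve(c(3000, 3500), c(0.9, 0.8), 1000)
  expect_equal(decode_peaks(two)$time_ms, 3000)
  expect_equal(oracle_decode(two), 3000)

  set.seed(42)
  for (rep_ in 1:200) {
    dur_s <- stats::runif(1, 10, 30)
    n <- round(dur_s * 100)
    k <- stats::rpois(1, 5) + 1L
    times <- sort(stats::runif(k, 200, dur_s * 1000 - 200))
    heights <- stats::runif(k, 0.1, 1.2)
    curve <- bump_curve(times, heights, n, sigma_ms = stats::runif(1, 30, 80))
    expect_equal(decode_peaks(curve)$time_ms, oracle_decode(curve))
  }
})

test_that("decode output spacing respects the minimum interval", {
  set.seed(7)
  for (rep_ in 1:20) {
    v <- stats::filter(stats::rnorm(3000), rep(1 / 30, 30), sides = 2)
    v[is.na(v)] <- 0
    curve <- gait_curve(as.numeric(v / max(abs(v))), 100)
    det <- decode_peaks(curve, min_height = 0.1, min_interval_ms = 700)
    if (nrow(det) > 1L) expect_gte(min(diff(det$time_ms)), 700)
  }
})

test_that("encode followed by decode is the identity on well-spaced events", {
  set.seed(11)
  for (rep_ in 1:10) {
    k <- sample(2:8, 1)
    gaps <- stats::runif(k, 1100, 2500)   # > min interval and > 8 sigma
    times <- round(cumsum(gaps) / 10) * 10  # on the 100 Hz grid
    ev <- gait_events(rep("R", k), rep("TO", k), times, source = "manual")
    n <- ceiling(max(times) / 10) + 100
    curve <- encode_events(ev, n, 100, side = "R", type = "TO")
    dec <- decode_peaks(curve)
    expect_equal(dec$time_ms, times)
    expect_identical(dec$side, rep("R", k))
    expect_identical(dec$type, rep("TO", k))
  }
})

test_that("curve correlation is Pearson and rejects degenerate input", {
  a <- bump_curve(2000, 1, 500)
  expect_equal(curve_correlation(a, a), 1)
  neg <- gait_curve(-a$values, a$rate_hz)
  expect_equal(curve_correlation(a, neg), -1)

  b <- bump_curve(2000 + 53.3, 1, 500)  # offset by one sigma
  # brute-force summation oracle for Pearson's r
  x <- a$values; y <- b$values; n <- length(x)
  r_oracle <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(curve_correlation(a, b), r_oracle, tolerance = 1e-12)

  flat <- gait_curve(rep(0.5, 500), 100)
  expect_error(curve_correlation(a, flat), "constant")
})
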