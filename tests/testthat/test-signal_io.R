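test_that("trial CSV round-trips losslessly and deterministically", {
  sim <- simulate_trial(quick_params(seed = 3L, noise_sd_N = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(sim$trial, path)
  back <- read_trial(path)
  expect_equal(back, sim$trial)

  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trial(sim$trial, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("mixed-rate trials (slow heel grid) survive the CSV layout", {
  grf <- gait_channel(sin(seq(0, 10, length.out = 101)) + 2, 100, "grf_vertical")
  heel <- gait_channel(cos(seq(0, 10, length.out = 21)), 20, "heel_height")
  trial <- gait_trial("mixed", 650, grf, grf, heel, heel, "exo")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(trial, path)
  back <- read_trial(path)
  expect_equal(back$channels$heel_left$rate_hz, 20)
  expect_equal(back$channels$heel_left$values, heel$values)
  expect_equal(back$body_weight_N, 650)
  expect_equal(length(back$channels$grf_left), 101L)
})

test_that("malformed trial files produce named errors", {
  sim <- simulate_trial(quick_params(seed = 4L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(sim$trial, path)
  lines <- readLines(path)

  # drop the heel_left_mm column
  drop_col <- function(l) {
    parts <- strsplit(l, ",", fixed = TRUE)[[1]]
    paste(parts[-4], collapse = ",")
  }
  hdr <- grep("^time_ms", lines)
  mangled <- c(lines[1:(hdr - 1)], vapply(lines[hdr:length(lines)], drop_col, ""))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(mangled, bad)
  expect_error(read_trial(bad), "heel_left_mm")

  # non-monotonic time column
  rows <- lines[(hdr + 1):length(lines)]
  swapped <- c(lines[1:hdr], rows[2], rows[1], rows[3:length(rows)])
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(swapped, bad2)
  expect_error(read_trial(bad2), "increasing")

  expect_error(read_trial(file.path(tempdir(), "nope.csv")), "no such file")
})

test_that("zero-phase Butterworth passes DC, attenuates per |H|^2, adds no lag", {
  rate <- 1000
  # DC gain 1: constant force unchanged
  const <- butter_zerophase(rep(700, 2000), rate, 20)
  expect_equal(const, rep(700, 2000), tolerance = 1e-9)

  # magnitude oracle: evaluate the digital transfer function on the unit
  # circle; two passes square the magnitude
  bf <- signal::butter(4, 2 * 20 / rate, type = "low")
  mag2 <- function(f_hz) {
    w <- 2 * pi * f_hz / rate
    z <- exp(-1i * w * (seq_along(bf$b) - 1))
    Mod(sum(bf$b * z) / sum(bf$a * z))^2
  }
  t <- seq_len(8000) / rate
  for (f in c(5, 50)) {
    y <- butter_zerophase(sin(2 * pi * f * t), rate, 20)
    core <- y[2001:6000]
    gain <- (max(core) - min(core)) / 2
    expect_equal(gain, mag2(f), tolerance = 1e-3)
  }
  # 50 Hz attenuated far below 5 Hz
  expect_lt(mag2(50), 0.01 * mag2(5))

  # zero phase: a symmetric pulse keeps its argmax
  pulse <- exp(-((seq_len(4001) - 2001) / 100)^2)
  expect_equal(which.max(butter_zerophase(pulse, rate, 20)), 2001L)
})

test_that("linear resampling has the expected length and exact endpoints", {
  n <- 31L
  ch <- gait_channel(sin(seq(0, 3, length.out = n)), 100, "heel_height")
  up <- resample_linear(ch, 1000)
  expect_equal(length(up), 10L * (n - 1L) + 1L)
  expect_equal(up$values[1], ch$values[1])
  expect_equal(up$values[length(up)], ch$values[n])
  # within the linear-interpolation error bound h^2 max|f''| / 8
  t_new <- (seq_along(up$values) - 1) / 1000
  bound <- (1 / 100)^2 * 10^2 / 8
  expect_lt(max(abs(up$values - sin(t_new * 10))), bound * 1.01)
})

test_that("preprocessing unifies rates onto a common grid", {
  sim <- simulate_trial(quick_params(seed = 5L, rate_hz = 200, noise_sd_N = 2))
  # heel collected at 100 Hz like a motion-capture system
  tr <- sim$trial
  tr$channels$heel_left <- resample_linear(tr$channels$heel_left, 100)
  tr$channels$heel_right <- resample_linear(tr$channels$heel_right, 100)
  pre <- preprocess_trial(tr, target_rate_hz = 200)
  lens <- vapply(pre$channels, length, integer(1))
  expect_true(all(lens == lens[1]))
  expect_equal(pre$rate_hz, 200)
  expect_equal(pre$channels$heel_left$rate_hz, 200)
})

test_that("preprocessing is idempotent on band-limited trials", {
  # a trial whose force content sits far below the 20 Hz cut-off, so a
  # second pass through the pipeline must leave it essentially unchanged
  # away from the ends
  t <- seq(0, 30, by = 1 / 200)
  grf <- gait_channel(400 + 300 * sin(2 * pi * 0.5 * t) + 50 * sin(2 * pi * 5 * t),
                      200, "grf_vertical")
  heel <- gait_channel(75 + 75 * sin(2 * pi * 0.5 * t), 200, "heel_height")
  tr <- gait_trial("bl", 700, grf, grf, heel, heel)
  pre <- preprocess_trial(tr, target_rate_hz = 200)
  twice <- preprocess_trial(pre, target_rate_hz = 200)
  n <- length(pre$channels$grf_left)
  interior <- seq.int(ceiling(n * 0.05), floor(n * 0.95))
  expect_lt(max(abs(twice$channels$grf_left$values[interior] -
                    pre$channels$grf_left$values[interior])), 0.5)
  expect_lt(max(abs(twice$channels$heel_left$values[interior] -
                    pre$channels$heel_left$values[interior])), 0.5)
})

test_that("heel smoothing preserves a clean swing arc within 1 mm RMS", {
  sim <- simulate_trial(clean_params(seed = 6L))
  h <- sim$trial$channels$heel_left$values
  sm <- gaitevents:::whittaker_smooth(h, 2)
  expect_lt(sqrt(mean((sm - h)^2)), 1)
})
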