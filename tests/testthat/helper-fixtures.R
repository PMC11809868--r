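# Shared fixtures, built in code at test time.

# Small, fast simulator settings: 30 s at 100 Hz (~14 strides/side).
quick_params <- function(seed = 1L, ...) {
  args <- list(duration_s = 30, rate_hz = 100, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_params, args)
}

clean_params <- function(seed = 1L, ...) {
  quick_params(seed = seed, noise_sd_N = 0, drag_rate = 0,
               cross_plate_rate = 0, stride_jitter_ms = 0, ...)
}

# A single Gaussian-bump curve with peaks of given heights (same sigma as
# the encoder default) at the given times.
bump_curve <- function(times_ms, heights, n, rate_hz = 100, sigma_ms = 53.3,
                       side = "L", type = "HS") {
  t_ms <- (seq_len(n) - 1) / rate_hz * 1000
  v <- numeric(n)
  for (k in seq_along(times_ms))
    v <- pmax(v, heights[k] * exp(-(t_ms - times_ms[k])^2 / (2 * sigma_ms^2)))
  gait_curve(v, rate_hz, side, type, sigma_ms)
}

# Independent brute-force oracle for constrained peak decoding: enumerate
# every admissible subset of candidate local maxima (pairwise spacing >=
# the minimum interval) and return the height-lexicographic maximum --
# heights compared sorted descending, ties broken toward earlier times.
oracle_decode <- function(curve, min_height = 0.3, min_interval_ms = 1000) {
  v <- curve$values
  n <- length(v)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j < n && v[j] > v[j + 1L] && v[i] >= min_height)
        cand <- c(cand, (i + j) %/% 2L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand)) return(numeric(0))
  gap <- min_interval_ms / 1000 * curve$rate_hz
  key <- function(sub) {  # sort key: heights desc, then times asc
    o <- order(-v[sub], sub)
    list(h = v[sub][o], t = sub[o])
  }
  better <- function(a, b) {  # TRUE if subset key a beats b
    la <- length(a$h); lb <- length(b$h)
    for (k in seq_len(min(la, lb))) {
      if (a$h[k] != b$h[k]) return(a$h[k] > b$h[k])
      if (a$t[k] != b$t[k]) return(a$t[k] < b$t[k])
    }
    la > lb
  }
  best <- NULL
  m <- length(cand)
  for (mask in 0:(2^m - 1)) {
    sub <- cand[bitwAnd(bitwShiftR(mask, seq_len(m) - 1L), 1L) == 1L]
    if (length(sub) > 1L && min(diff(sub)) < gap) next
    k <- key(sub)
    if (is.null(best) || better(k, best)) best <- k
  }
  sort((best$t - 1) / curve$rate_hz * 1000)
}
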