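# Trial CSV dialect: UTF-8, comma separators, dot decimal, one header row,
# preceded by `# key: value` metadata lines (trial_id, condition,
# body_weight_N, rate_hz, heel_rate_hz).  The time_ms column is the GRF
# grid; when the heel rate is lower, heel cells are empty except every
# (rate_hz / heel_rate_hz)-th row.

#' Write a walking trial to CSV
#'
#' Numeric values are written with 12 significant digits so that
#' [read_trial()] round-trips them losslessly; repeated writes of the same
#' trial produce byte-identical files.
#'
#' @param trial A [gait_trial()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "gait_trial"))
  ch <- trial$channels
  grf_rate <- ch$grf_left$rate_hz
  heel_rate <- ch$heel_left$rate_hz
  if (ch$grf_right$rate_hz != grf_rate || ch$heel_right$rate_hz != heel_rate)
    stop("left/right channel rates differ within a kind; cannot serialize",
         call. = FALSE)
  if (heel_rate > grf_rate)
    stop("heel rate above GRF rate is not supported by the CSV layout",
         call. = FALSE)
  step <- grf_rate / heel_rate
  if (abs(step - round(step)) > 1e-9)
    stop("GRF rate must be an integer multiple of the heel rate", call. = FALSE)
  step <- as.integer(round(step))

  n <- max(length(ch$grf_left$values), length(ch$grf_right$values))
  num <- function(x) sprintf("%.12g", x)
  col <- function(v, at = NULL) {
    out <- character(n)
    if (is.null(at)) {
      out[seq_along(v)] <- num(v)
    } else {
      idx <- at[at <= n][seq_len(min(length(v), sum(at <= n)))]
      out[idx] <- num(v[seq_along(idx)])
    }
    out
  }
  heel_rows <- seq(1L, by = step, length.out = length(ch$heel_left$values))
  if (max(heel_rows) > n)
    stop("heel channel extends past the GRF channel", call. = FALSE)

  lines <- c(
    sprintf("# trial_id: %s", trial$trial_id),
    sprintf("# condition: %s", trial$condition),
    sprintf("# body_weight_N: %s", num(trial$body_weight_N)),
    sprintf("# rate_hz: %s", num(grf_rate)),
    sprintf("# heel_rate_hz: %s", num(heel_rate)),
    "time_ms,grf_left_N,grf_right_N,heel_left_mm,heel_right_mm",
    paste(num((seq_len(n) - 1) / grf_rate * 1000),
          col(ch$grf_left$values), col(ch$grf_right$values),
          col(ch$heel_left$values, heel_rows),
          col(ch$heel_right$values, heel_rows),
          sep = ",")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a walking trial from CSV
#'
#' @param path Path to a trial CSV produced by [write_trial()] (or any file
#'   following the same dialect).
#' @return A [gait_trial()] with channels at their native rates.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", raw, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ml))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  for (key in c("body_weight_N", "rate_hz"))
    if (is.null(meta[[key]]))
      stop(sprintf("trial file is missing metadata line '# %s: ...'", key),
           call. = FALSE)

  body <- raw[!grepl("^#", raw)]
  body <- body[nzchar(body)]
  if (length(body) < 2L) stop("trial file has no data rows", call. = FALSE)
  header <- strsplit(body[[1]], ",", fixed = TRUE)[[1]]
  required <- c("time_ms", "grf_left_N", "grf_right_N", "heel_left_mm", "heel_right_mm")
  missing <- setdiff(required, header)
  if (length(missing))
    stop(sprintf("trial file is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         check.names = FALSE, colClasses = "numeric")

  tm <- tab$time_ms
  if (any(diff(tm) <= 0))
    stop("time_ms column must be strictly increasing", call. = FALSE)

  rate <- as.numeric(meta$rate_hz)
  heel_rate <- if (is.null(meta$heel_rate_hz)) rate else as.numeric(meta$heel_rate_hz)
  take <- function(colname, kind, r) {
    v <- tab[[colname]]
    v <- v[!is.na(v)]
    gait_channel(v, r, kind)
  }
  gait_trial(
    trial_id = if (is.null(meta$trial_id)) basename(path) else meta$trial_id,
    body_weight_N = as.numeric(meta$body_weight_N),
    condition = if (is.null(meta$condition)) "no_exo" else meta$condition,
    grf_left = take("grf_left_N", "grf_vertical", rate),
    grf_right = take("grf_right_N", "grf_vertical", rate),
    heel_left = take("heel_left_mm", "heel_height", heel_rate),
    heel_right = take("heel_right_mm", "heel_height", heel_rate)
  )
}
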