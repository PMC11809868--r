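#' Construct a gait event set
#'
#' A labeled collection of heel-strike (HS) and toe-off (TO) times.  Within
#' one (side, type) stream, times must be strictly increasing.
#'
#' @param side Character vector, `"L"` or `"R"`.
#' @param type Character vector, `"HS"` or `"TO"`.
#' @param time_ms Numeric vector of event times in milliseconds (>= 0).
#' @param source Provenance of the labels: `"manual"`, `"threshold"`,
#'   `"model"`, or `"truth"`.
#' @return A data frame of class `gait_events` with columns
#'   `side`, `type`, `time_ms`, ordered by time.
#' @export
gait_events <- function(side = character(), type = character(),
                        time_ms = numeric(),
                        source = c("manual", "threshold", "model", "truth")) {
  source <- match.arg(source)
  stopifnot(length(side) == length(type), length(type) == length(time_ms))
  side <- as.character(side); type <- as.character(type)
  if (!all(side %in% c("L", "R"))) stop("side must be 'L' or 'R'", call. = FALSE)
  if (!all(type %in% c("HS", "TO"))) stop("type must be 'HS' or 'TO'", call. = FALSE)
  if (any(time_ms < 0)) stop("event times must be non-negative", call. = FALSE)
  df <- data.frame(side = side, type = type, time_ms = as.numeric(time_ms),
                   stringsAsFactors = FALSE)
  df <- df[order(df$time_ms, df$side, df$type), , drop = FALSE]
  rownames(df) <- NULL
  for (s in unique(df$side)) for (ty in unique(df$type)) {
    tt <- df$time_ms[df$side == s & df$type == ty]
    if (length(tt) > 1L && any(diff(tt) <= 0))
      stop(sprintf("event times within stream (%s, %s) must be strictly increasing", s, ty),
           call. = FALSE)
  }
  structure(df, class = c("gait_events", "data.frame"), source = source)
}

#' Extract one (side, type) stream of event times
#' @param events A [gait_events()] set.
#' @param side `"L"` or `"R"`.
#' @param type `"HS"` or `"TO"`.
#' @return Sorted numeric vector of event times (ms).
#' @export
event_stream <- function(events, side, type) {
  stopifnot(inherits(events, "gait_events"))
  sort(events$time_ms[events$side == side & events$type == type])
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d events (source: %s)\n", nrow(x), attr(x, "source")))
  for (s in c("L", "R")) for (ty in c("HS", "TO")) {
    n <- sum(x$side == s & x$type == ty)
    if (n) cat(sprintf("  %s %s: %d\n", s, ty, n))
  }
  invisible(x)
}

#' Write / read event sets as CSV (`side,type,time_ms`)
#' @param events A [gait_events()] set.
#' @param path File path.
#' @return `write_events()`: invisibly `path`; `read_events()`: a `gait_events` set.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "gait_events"))
  lines <- c(sprintf("# source: %s", attr(events, "source")),
             "side,type,time_ms",
             sprintf("%s,%s,%.12g", events$side, events$type, events$time_ms))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  src <- "manual"
  m <- grep("^#\\s*source\\s*:", raw, value = TRUE)
  if (length(m)) src <- trimws(sub("^#\\s*source\\s*:", "", m[[1]]))
  body <- raw[!grepl("^#", raw)]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE)
  gait_events(tab$side, tab$type, tab$time_ms, source = src)
}
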