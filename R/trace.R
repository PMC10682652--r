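#' Sampled physiologic trace
#'
#' Container for one physiologic channel -- ascending-aorta pressure (mmHg),
#' LVOT Doppler velocity envelope (cm/s) or ECG (arbitrary units) -- sampled
#' at strictly increasing times, with optional ECG R-peak annotations used to
#' gate beat segmentation.
#'
#' @param times Numeric vector of sample times in seconds, strictly increasing.
#' @param values Numeric vector of samples, same length as `times`.
#'   Pressure must be strictly positive; the velocity envelope non-negative.
#' @param channel One of `"pressure"`, `"velocity"`, `"ecg"`.
#' @param r_peaks Optional numeric vector of R-peak times (seconds), strictly
#'   increasing, each inside the sampled interval, consecutive intervals
#'   longer than 0.2 s.
#' @return An object of class `sampled_trace`.
#' @examples
#' tr <- sampled_trace(seq(0, 1, 0.01), 80 + 20 * sin(seq(0, 1, 0.01) * pi),
#'                     "pressure", r_peaks = c(0, 0.99))
#' print(tr)
#' @export
sampled_trace <- function(times, values, channel = c("pressure", "velocity", "ecg"),
                          r_peaks = NULL) {
  channel <- match.arg(channel)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) == 0L) stop_vp("empty trace: no samples")
  if (length(times) != length(values))
    stop_vp("times (%d) and values (%d) differ in length", length(times), length(values))
  if (anyNA(times) || anyNA(values)) stop_vp("trace contains missing values")
  if (any(diff(times) <= 0))
    stop_vp("times must be strictly increasing (first violation at sample %d)",
            which(diff(times) <= 0)[1] + 1L)
  if (channel == "pressure" && any(values <= 0))
    stop_vp("pressure values must be strictly positive")
  if (channel == "velocity" && any(values < 0))
    stop_vp("velocity envelope values must be non-negative")
  if (!is.null(r_peaks)) {
    r_peaks <- as.numeric(r_peaks)
    if (any(diff(r_peaks) <= 0)) stop_vp("r_peaks must be strictly increasing")
    if (length(r_peaks) > 1 && any(diff(r_peaks) <= 0.2))
      stop_vp("consecutive R-R intervals must exceed 0.2 s")
    if (any(r_peaks < times[1] | r_peaks > times[length(times)]))
      stop_vp("r_peaks must lie within the sampled time range")
  }
  structure(list(channel = channel, times = times, values = values,
                 r_peaks = r_peaks), class = "sampled_trace")
}

#' @export
print.sampled_trace <- function(x, ...) {
  cat(sprintf("<sampled_trace> channel=%s, %d samples over %.3f s, %d R-peaks\n",
              x$channel, length(x$times), diff(range(x$times)),
              length(x$r_peaks %||% numeric(0))))
  invisible(x)
}

split_fields <- function(line) {
  sep <- if (grepl("\t", line)) "\t" else if (grepl(";", line)) ";" else ","
  strsplit(line, sep, fixed = TRUE)[[1]]
}

# Parse a two-column numeric delimited file, rejecting malformed rows with the
# offending line number.  Delimiter (comma/semicolon/tab) is autodetected and
# a single non-numeric header row is tolerated.
parse_two_column <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_vp("empty file: %s", path)
  first <- suppressWarnings(as.numeric(split_fields(lines[1])))
  start <- if (anyNA(first)) 2L else 1L
  if (start > length(lines)) stop_vp("no data rows in %s", path)
  out <- matrix(NA_real_, nrow = length(lines) - start + 1L, ncol = 2L)
  for (i in seq(start, length(lines))) {
    f <- suppressWarnings(as.numeric(split_fields(lines[i])))
    if (length(f) < 2L || anyNA(f[1:2]))
      stop_vp("malformed row at line %d of %s: '%s'", i, path, lines[i])
    out[i - start + 1L, ] <- f[1:2]
  }
  out
}

#' Read a physiologic trace from delimited text
#'
#' Reads a two-column (time in seconds, value) comma/semicolon/tab-delimited
#' file, with an optional single-column R-peak annotation file.  Non-numeric
#' rows are rejected with their line number; non-increasing times are a
#' validation error, never silently re-sorted.
#'
#' @param path Path to the two-column trace file (optional header row).
#' @param channel Channel of the trace; see [sampled_trace()].
#' @param r_peak_path Optional path to a one-column file of R-peak times (s).
#' @return A [sampled_trace()].
#' @export
read_trace <- function(path, channel = c("pressure", "velocity", "ecg"),
                       r_peak_path = NULL) {
  channel <- match.arg(channel)
  m <- parse_two_column(path)
  r <- NULL
  if (!is.null(r_peak_path)) {
    rl <- readLines(r_peak_path, warn = FALSE)
    rl <- rl[nzchar(trimws(rl))]
    r <- suppressWarnings(as.numeric(rl))
    if (anyNA(r)) {
      if (length(rl) >= 1 && is.na(suppressWarnings(as.numeric(rl[1]))))
        r <- suppressWarnings(as.numeric(rl[-1]))
      if (anyNA(r)) stop_vp("non-numeric R-peak entries in %s", r_peak_path)
    }
  }
  sampled_trace(m[, 1], m[, 2], channel, r_peaks = r)
}

#' Write a trace to delimited text
#'
#' Inverse of [read_trace()]: writes `time_s,value` rows (and optionally the
#' R-peak annotation file).  The numeric text representation uses 17
#' significant digits so a write/read round trip is bit-exact.
#'
#' @param trace A [sampled_trace()].
#' @param path Output file for the two-column trace.
#' @param r_peak_path Optional output file for R-peak times.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, r_peak_path = NULL) {
  stopifnot(inherits(trace, "sampled_trace"))
  lines <- c("time_s,value",
             sprintf("%.17g,%.17g", trace$times, trace$values))
  writeLines(lines, path)
  if (!is.null(r_peak_path) && !is.null(trace$r_peaks))
    writeLines(sprintf("%.17g", trace$r_peaks), r_peak_path)
  invisible(path)
}

#' Read digitized curve points with optional axis calibration
#'
#' Reads an x,y point list as exported by common plot digitizers.  When the
#' exported coordinates are in plot-axis units, an affine calibration maps two
#' reference abscissae `x` to times `t` (seconds) and two reference ordinates
#' `y` to values `v` (channel units).
#'
#' @param path Two-column delimited file of digitized points.
#' @param channel Channel of the digitized curve.
#' @param calibration `NULL` if x is already seconds and y channel units,
#'   else `list(x = c(x0, x1), t = c(t0, t1), y = c(y0, y1), v = c(v0, v1))`.
#' @return A [sampled_trace()] (no R-peaks).
#' @export
read_digitized <- function(path, channel = c("pressure", "velocity", "ecg"),
                           calibration = NULL) {
  channel <- match.arg(channel)
  m <- parse_two_column(path)
  x <- m[, 1]; y <- m[, 2]
  if (!is.null(calibration)) {
    cb <- calibration
    for (nm in c("x", "t", "y", "v"))
      if (length(cb[[nm]]) != 2L) stop_vp("calibration$%s must have two reference values", nm)
    if (diff(cb$x) == 0 || diff(cb$y) == 0) stop_vp("degenerate calibration references")
    x <- cb$t[1] + (x - cb$x[1]) * diff(cb$t) / diff(cb$x)
    y <- cb$v[1] + (y - cb$y[1]) * diff(cb$v) / diff(cb$y)
  }
  sampled_trace(x, y, channel)
}

#' Detect ECG R-peaks
#'
#' Local-maximum detector with an adaptive threshold: a sample is a candidate
#' peak if it exceeds both neighbours and exceeds mean + 2.5 SD of the
#' rectified signal in a sliding 2-s window centred on it; candidates closer
#' than the refractory period are resolved in favour of the taller peak.
#' Intended for clean synthetic or laboratory signals; a manual annotation
#' file (see [read_trace()]) always overrides automatic detection.
#'
#' @param ecg A [sampled_trace()] with `channel = "ecg"` spanning at least 2 s.
#' @param refractory Minimum peak separation in seconds (default 0.2).
#' @param k Threshold multiplier on the windowed SD (default 2.5).
#' @return Numeric vector of R-peak times in seconds.
#' @export
detect_r_peaks <- function(ecg, refractory = 0.2, k = 2.5) {
  stopifnot(inherits(ecg, "sampled_trace"))
  if (ecg$channel != "ecg") stop_vp("detect_r_peaks expects an ecg trace")
  t <- ecg$times; v <- ecg$values
  if (diff(range(t)) < 2) stop_vp("need at least 2 s of ECG signal")
  rect <- abs(v - stats::median(v))
  n <- length(v)
  cand <- which(v[-c(1, n)] > v[-c(n - 1, n)] & v[-c(1, n)] > v[-c(1, 2)]) + 1L
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    win <- rect[t >= t[i] - 1 & t <= t[i] + 1]
    keep[j] <- rect[i] > mean(win) + k * stats::sd(win)
  }
  cand <- cand[keep]
  if (length(cand) == 0L)
    stop_vp("no R-peak found; supply a manual R-peak annotation file")
  # refractory: greedy by amplitude
  ord <- cand[order(v[cand], decreasing = TRUE)]
  taken <- numeric(0)
  for (i in ord)
    if (all(abs(t[i] - taken) >= refractory)) taken <- c(taken, t[i])
  sort(taken)
}
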