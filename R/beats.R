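#' Single-beat containers
#'
#' A `vp_beat` holds one cardiac cycle of a trace, re-expressed relative to
#' its gating R-peak (relative time 0).  A `vp_meshed_beat` is a beat
#' linearly interpolated onto a uniform mesh of relative times spanning
#' `[0, duration]`, so that pressure and velocity beats can be paired
#' point-by-point.
#'
#' @param channel Channel of the beat.
#' @param rel_times Seconds since the beat's R-peak; starts at 0, strictly
#'   increasing, at least 16 samples.
#' @param values Channel values, one per time.
#' @return `vp_beat()` returns an object of class `vp_beat`.
#' @export
vp_beat <- function(channel, rel_times, values) {
  rel_times <- as.numeric(rel_times); values <- as.numeric(values)
  if (length(rel_times) < 16L) stop_vp("a beat needs at least 16 samples, got %d", length(rel_times))
  if (rel_times[1] != 0) stop_vp("beat rel_times must start at 0")
  if (any(diff(rel_times) <= 0)) stop_vp("beat rel_times must be strictly increasing")
  if (length(rel_times) != length(values)) stop_vp("rel_times/values length mismatch")
  structure(list(channel = channel, rel_times = rel_times, values = values),
            class = "vp_beat")
}

#' Segment a trace into R-gated beats
#'
#' Cuts the trace at its annotated R-peaks: beat *i* contains the samples in
#' `[r_i, r_{i+1})` with times re-expressed relative to `r_i`.  Samples after
#' the last R-peak (the final partial beat) are discarded.  A sample is
#' anchored at relative time 0 by interpolation when no sample falls exactly
#' on the R-peak.
#'
#' @param trace A [sampled_trace()] with at least two R-peaks.
#' @return List of [vp_beat()] objects, one per R-R interval.
#' @export
segment_beats <- function(trace) {
  stopifnot(inherits(trace, "sampled_trace"))
  r <- trace$r_peaks
  if (is.null(r) || length(r) < 2L)
    stop_vp("segmentation needs at least 2 R-peaks (got %d)", length(r %||% numeric(0)))
  lapply(seq_len(length(r) - 1L), function(i) {
    sel <- trace$times >= r[i] & trace$times < r[i + 1]
    tt <- trace$times[sel] - r[i]
    vv <- trace$values[sel]
    if (length(tt) == 0L || tt[1] > 0) {
      # anchor the beat at the R-peak itself
      v0 <- stats::approx(trace$times, trace$values, xout = r[i], rule = 2)$y
      tt <- c(0, tt); vv <- c(v0, vv)
    }
    vp_beat(trace$channel, tt, vv)
  })
}

#' Interpolate a beat onto a uniform mesh
#'
#' Linear interpolation of the beat onto `n_points` equally spaced relative
#' times over `[0, duration]` (duration = last sample's relative time).  The
#' first and last sample values are preserved exactly.  The common mesh is
#' what lets simultaneous pressure and velocity beats be paired into a loop
#' with the same number of coincident points in time.
#'
#' @param beat A [vp_beat()].
#' @param n_points Mesh size, at least 16 (default 256, resolving 1-2 ms
#'   features at typical heart rates).
#' @return An object of class `vp_meshed_beat` with fields `channel`, `mesh`
#'   and `values`.
#' @export
mesh_beat <- function(beat, n_points = 256) {
  stopifnot(inherits(beat, "vp_beat"))
  if (n_points < 16) stop_vp("n_points must be at least 16, got %d", n_points)
  dur <- beat$rel_times[length(beat$rel_times)]
  if (dur <= 0) stop_vp("beat duration must be positive")
  mesh <- seq(0, dur, length.out = n_points)
  vals <- stats::approx(beat$rel_times, beat$values, xout = mesh)$y
  vals[1] <- beat$values[1]
  vals[n_points] <- beat$values[length(beat$values)]
  structure(list(channel = beat$channel, mesh = mesh, values = vals),
            class = "vp_meshed_beat")
}

#' Ensemble-average meshed beats
#'
#' Pointwise arithmetic mean of meshed beats on a mesh normalized to the
#' median beat duration: mesh index *k* of every beat is treated as the same
#' cardiac phase, so beats of slightly unequal R-R duration contribute
#' without diastolic smearing.  Twenty beats is the expected practice for a
#' final averaged measurement; fewer triggers a warning, never a silent
#' result.
#'
#' @param beats List of `vp_meshed_beat` objects sharing channel and mesh size.
#' @param expected Number of beats below which a warning is issued (default 20).
#' @return A single `vp_meshed_beat`.
#' @export
average_beats <- function(beats, expected = 20) {
  if (length(beats) < 1L) stop_vp("need at least one beat to average")
  stopifnot(all(vapply(beats, inherits, logical(1), "vp_meshed_beat")))
  ch <- unique(vapply(beats, `[[`, character(1), "channel"))
  if (length(ch) != 1L) stop_vp("cannot average mixed channels: %s", paste(ch, collapse = ", "))
  np <- unique(vapply(beats, function(b) length(b$mesh), integer(1)))
  if (length(np) != 1L) stop_vp("beats must share mesh size")
  if (length(beats) < expected)
    warning(sprintf("averaging %d beats (fewer than the expected %d)",
                    length(beats), expected), call. = FALSE)
  durs <- vapply(beats, function(b) b$mesh[length(b$mesh)], numeric(1))
  mesh <- seq(0, stats::median(durs), length.out = np)
  vals <- rowMeans(vapply(beats, `[[`, numeric(np), "values"))
  structure(list(channel = ch, mesh = mesh, values = vals),
            class = "vp_meshed_beat")
}
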