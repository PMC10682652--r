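#' Build a velocity-pressure loop
#'
#' Pairs one averaged LVOT-velocity beat with one averaged aortic-pressure
#' beat on their shared mesh.  Traversing the `(velocity, pressure)` pairs
#' over the cardiac cycle draws the VP loop; its geometry (angles, chord
#' lengths between the pressure/velocity extrema) quantifies the coupling of
#' flow across the stenotic valve with the pressure just distal to it.
#'
#' @param pressure_beat,velocity_beat `vp_meshed_beat` objects from
#'   [average_beats()] (or [mesh_beat()]), with identical mesh length and
#'   durations within 10% of each other.
#' @return An object of class `vp_loop` with fields `mesh` (relative seconds,
#'   taken from the pressure beat), `velocity` (cm/s) and `pressure` (mmHg).
#'   No re-interpolation is performed: mesh index k of the two channels is
#'   paired as the same cardiac phase.
#' @export
build_loop <- function(pressure_beat, velocity_beat) {
  stopifnot(inherits(pressure_beat, "vp_meshed_beat"),
            inherits(velocity_beat, "vp_meshed_beat"))
  if (pressure_beat$channel != "pressure" || velocity_beat$channel != "velocity")
    stop_vp("build_loop expects a pressure beat and a velocity beat")
  np <- length(pressure_beat$mesh); nv <- length(velocity_beat$mesh)
  if (np != nv) stop_vp("mesh lengths differ (%d vs %d)", np, nv)
  dp <- pressure_beat$mesh[np]; dv <- velocity_beat$mesh[nv]
  if (abs(dp - dv) / max(dp, dv) > 0.10)
    stop_vp("beat durations differ by more than 10%% (%.3f vs %.3f s); re-segment the traces",
            dp, dv)
  structure(list(mesh = pressure_beat$mesh,
                 velocity = velocity_beat$values,
                 pressure = pressure_beat$values),
            class = "vp_loop")
}

#' @export
print.vp_loop <- function(x, ...) {
  cat(sprintf("<vp_loop> %d points over %.3f s; V in [%.1f, %.1f] cm/s, P in [%.1f, %.1f] mmHg\n",
              length(x$mesh), x$mesh[length(x$mesh)],
              min(x$velocity), max(x$velocity), min(x$pressure), max(x$pressure)))
  invisible(x)
}

#' Extract the loop landmarks
#'
#' Landmarks of the averaged cycle: `Vmax` the peak LVOT velocity and `t_Vmax`
#' its time from the R-peak (first index on ties); `Pmax` the peak aortic
#' pressure at `t_Pmax`; `P_Vmax` the pressure at `t_Vmax`; `V_Pmax` the
#' velocity at `t_Pmax`; `Vo` the velocity at ejection onset, taken as the
#' first mesh point where the envelope reaches `vo_frac` of `Vmax`; and
#' `P_Vo` the minimum (diastolic) pressure of the beat, the paper-stated
#' pressure reference at ejection onset.
#'
#' @param loop A [build_loop()] result.
#' @param vo_frac Ejection-onset threshold as a fraction of `Vmax`
#'   (default 0.05, robust to envelope baseline noise).
#' @return Object of class `vp_landmarks`.
#' @export
extract_landmarks <- function(loop, vo_frac = 0.05) {
  stopifnot(inherits(loop, "vp_loop"))
  v <- loop$velocity; p <- loop$pressure; m <- loop$mesh
  if (all(v == 0)) stop_vp("degenerate loop: velocity identically zero")
  iv <- which.max(v)                      # first index on ties
  ip <- which.max(p)
  io <- which(v >= vo_frac * v[iv])[1]
  lm <- list(Vmax = v[iv], t_Vmax = m[iv],
             Vo = v[io], t_Vo = m[io],
             P_Vo = min(p),
             P_Vmax = p[iv],
             Pmax = p[ip], t_Pmax = m[ip],
             V_Pmax = v[ip])
  structure(lm, class = "vp_landmarks")
}

#' @export
print.vp_landmarks <- function(x, ...) {
  cat(sprintf(paste0("<vp_landmarks> Vmax=%.1f cm/s @ %.3f s, Vo=%.1f cm/s @ %.3f s\n",
                     "  P_Vo=%.1f, P_Vmax=%.1f, Pmax=%.1f mmHg @ %.3f s\n"),
              x$Vmax, x$t_Vmax, x$Vo, x$t_Vo, x$P_Vo, x$P_Vmax, x$Pmax, x$t_Pmax))
  invisible(x)
}

#' Loop angles and the [P(Vmax) - P(Vo)]/Vmax index
#'
#' Computes the VP-loop features on the native-unit axes (velocity in cm/s on
#' the abscissa, pressure in mmHg on the ordinate, 1 cm/s equivalent to
#' 1 mmHg in axis units, angles measured from the velocity axis):
#' * `slope_index` = (P_Vmax - P_Vo)/Vmax, the afterload index (mmHg per cm/s);
#' * `alpha_deg` = atan(slope_index), so tan(ALPHA) is *identically* the
#'   index -- the two are interchangeable parameters;
#' * `dP_ejection` = P_Vmax - P_Vo and `late_rise` = Pmax - P_Vmax (mmHg);
#' * `beta_deg`, the late-systolic chord angle from (Vmax, P_Vmax) to
#'   (V_Pmax, Pmax); `gala_deg`, the global chord angle from (0, P_Vo) to
#'   (V_Pmax, Pmax).  The BETA/GALA chord definitions are provisional
#'   stand-ins built from the named landmarks (the original intraoperative
#'   monitoring literature does not print closed forms) and are isolated here
#'   so they can be swapped.
#'
#' @param landmarks A [extract_landmarks()] result (or any list with the same
#'   fields); `Vmax` must be positive.
#' @return Object of class `vp_features` with the fields above plus the
#'   landmarks.
#' @export
compute_features <- function(landmarks) {
  lm <- landmarks
  if (!is_number(lm$Vmax) || lm$Vmax <= 0) stop_vp("Vmax must be positive")
  slope <- (lm$P_Vmax - lm$P_Vo) / lm$Vmax
  structure(list(
    alpha_deg = atan(slope) * 180 / pi,
    beta_deg = atan2(lm$Pmax - lm$P_Vmax, lm$Vmax - lm$V_Pmax) * 180 / pi,
    gala_deg = atan2(lm$Pmax - lm$P_Vo, lm$V_Pmax) * 180 / pi,
    dP_ejection = lm$P_Vmax - lm$P_Vo,
    slope_index = slope,
    late_rise = lm$Pmax - lm$P_Vmax,
    landmarks = lm), class = "vp_features")
}

#' @export
print.vp_features <- function(x, ...) {
  cat(sprintf(paste0("<vp_features> [P(Vmax)-P(Vo)]/Vmax = %.3f mmHg/(cm/s)\n",
                     "  ALPHA=%.2f deg, BETA=%.2f deg, GALA=%.2f deg\n",
                     "  P(Vmax)-P(Vo)=%.1f mmHg, Pmax-P(Vmax)=%.1f mmHg\n"),
              x$slope_index, x$alpha_deg, x$beta_deg, x$gala_deg,
              x$dP_ejection, x$late_rise))
  invisible(x)
}

#' Flatten loop features to a named record
#'
#' Units are embedded in the key names; suitable for JSON export.
#' @param x A `vp_features` object.
#' @param ... Unused.
#' @export
as.list.vp_features <- function(x, ...) {
  lm <- x$landmarks
  list(alpha_deg = x$alpha_deg, beta_deg = x$beta_deg, gala_deg = x$gala_deg,
       slope_index_mmHg_per_cm_s = x$slope_index,
       dP_ejection_mmHg = x$dP_ejection, late_rise_mmHg = x$late_rise,
       Vmax_cm_s = lm$Vmax, t_Vmax_s = lm$t_Vmax,
       Vo_cm_s = lm$Vo, t_Vo_s = lm$t_Vo,
       P_Vo_mmHg = lm$P_Vo, P_Vmax_mmHg = lm$P_Vmax,
       Pmax_mmHg = lm$Pmax, t_Pmax_s = lm$t_Pmax, V_Pmax_cm_s = lm$V_Pmax)
}

#' Pressure at peak velocity via R-wave timing
#'
#' The simplified clinical estimate of P(Vmax): both the pressure and the
#' Doppler recordings carry a simultaneous ECG, so the R-to-peak-velocity
#' interval measured on the Doppler envelope can be applied directly to the
#' pressure recording.  For each pressure beat the pressure is read (by
#' linear interpolation) at `r_peak + t_r_to_vmax` and the mean across beats
#' is returned.
#'
#' @param pressure A pressure [sampled_trace()] with R-peak annotations.
#' @param t_r_to_vmax R-to-Vmax interval in seconds; must be non-negative and
#'   shorter than every R-R interval it is applied to.
#' @return Mean pressure (mmHg) at the offset across beats.
#' @export
pressure_at_vmax_by_rwave <- function(pressure, t_r_to_vmax) {
  stopifnot(inherits(pressure, "sampled_trace"))
  if (pressure$channel != "pressure") stop_vp("expected a pressure trace")
  r <- pressure$r_peaks
  if (is.null(r) || length(r) < 1L) stop_vp("pressure trace has no R-peaks")
  if (!is_number(t_r_to_vmax) || t_r_to_vmax < 0) stop_vp("t_r_to_vmax must be >= 0")
  if (length(r) >= 2L) {
    if (t_r_to_vmax >= min(diff(r)))
      stop_vp("offset %.3f s exceeds the shortest R-R interval (%.3f s)",
              t_r_to_vmax, min(diff(r)))
    r <- r[-length(r)]                   # last beat is incomplete
  }
  xo <- r + t_r_to_vmax
  if (any(xo > pressure$times[length(pressure$times)]))
    stop_vp("offset extends beyond the recorded pressure trace")
  mean(stats::approx(pressure$times, pressure$values, xout = xo)$y)
}

#' Plot a VP loop with landmark annotations
#'
#' @param x A `vp_loop`.
#' @param features Optional [compute_features()] result to annotate.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.vp_loop <- function(x, features = NULL, ...) {
  graphics::plot(x$velocity, x$pressure, type = "l",
                 xlab = "LVOT velocity (cm/s)", ylab = "Aortic pressure (mmHg)",
                 main = "Velocity-pressure loop", ...)
  if (!is.null(features)) {
    lm <- features$landmarks
    graphics::points(c(lm$Vmax, lm$V_Pmax, 0), c(lm$P_Vmax, lm$Pmax, lm$P_Vo),
                     pch = 19, col = c("red", "blue", "darkgreen"))
    graphics::segments(0, lm$P_Vo, lm$Vmax, lm$P_Vmax, lty = 2, col = "red")
    graphics::legend("topleft", bty = "n", cex = 0.8, legend = sprintf(
      "ALPHA %.1f°  [P(Vmax)-P(Vo)]/Vmax %.3f", features$alpha_deg,
      features$slope_index))
  }
  invisible(x)
}
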