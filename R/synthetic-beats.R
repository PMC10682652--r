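#' Parameters of the synthetic beat-pair generator
#'
#' Morphological parameters of one cardiac cycle used by [gen_beat_pair()].
#' Defaults describe a severe-aortic-stenosis adult in sinus rhythm: heart
#' rate 75 bpm, aortic pressure 130/70 mmHg with a slow (pulsus tardus)
#' 300 ms systolic upstroke starting 80 ms after the R-peak, a dicrotic
#' notch, and a diastolic exponential decay; the LVOT envelope peaks at
#' 80 cm/s with ejection onset 50 ms after the R-peak, a prolonged 150 ms
#' acceleration time and 320 ms ejection.  `severity_decoupling` adds extra
#' lag of the pressure rise relative to the velocity peak: the larger it is,
#' the lower the pressure already attained at Vmax, hence the smaller
#' [P(Vmax) - P(Vo)]/Vmax -- the generator's severity dial.
#'
#' @param heart_rate Beats per minute.
#' @param Pdia,Psys Diastolic and systolic aortic pressure, mmHg.
#' @param pressure_upstroke_delay Seconds from R-peak to the foot of the
#'   pressure upstroke.
#' @param pressure_rise_time Upstroke duration, seconds.
#' @param dicrotic_notch_depth Notch depth as a fraction of pulse pressure.
#' @param diastolic_decay_tau Diastolic decay time constant, seconds.
#' @param Vpeak Peak LVOT velocity, cm/s.
#' @param ejection_onset_delay Seconds from R-peak to ejection onset.
#' @param ejection_duration Ejection duration, seconds.
#' @param acceleration_time Seconds from ejection onset to peak velocity
#'   (must be shorter than the ejection duration).
#' @param severity_decoupling Extra pressure lag, seconds.
#' @return Validated list of class `beat_params`.
#' @export
beat_params <- function(heart_rate = 75, Pdia = 70, Psys = 130,
                        pressure_upstroke_delay = 0.08,
                        pressure_rise_time = 0.30,
                        dicrotic_notch_depth = 0.12,
                        diastolic_decay_tau = 0.5,
                        Vpeak = 80, ejection_onset_delay = 0.05,
                        ejection_duration = 0.32, acceleration_time = 0.15,
                        severity_decoupling = 0) {
  p <- list(heart_rate = heart_rate, Pdia = Pdia, Psys = Psys,
            pressure_upstroke_delay = pressure_upstroke_delay,
            pressure_rise_time = pressure_rise_time,
            dicrotic_notch_depth = dicrotic_notch_depth,
            diastolic_decay_tau = diastolic_decay_tau,
            Vpeak = Vpeak, ejection_onset_delay = ejection_onset_delay,
            ejection_duration = ejection_duration,
            acceleration_time = acceleration_time,
            severity_decoupling = severity_decoupling)
  T <- 60 / heart_rate
  pos <- c("heart_rate", "Psys", "Pdia", "pressure_upstroke_delay",
           "pressure_rise_time", "diastolic_decay_tau", "Vpeak",
           "ejection_onset_delay", "ejection_duration", "acceleration_time")
  for (f in pos) if (!is_number(p[[f]]) || p[[f]] <= 0) stop_vp("%s must be positive", f)
  if (severity_decoupling < 0) stop_vp("severity_decoupling must be non-negative")
  if (Pdia >= Psys) stop_vp("Pdia must be below Psys")
  if (acceleration_time >= ejection_duration)
    stop_vp("acceleration_time must be shorter than ejection_duration")
  if (dicrotic_notch_depth < 0 || dicrotic_notch_depth > 0.5)
    stop_vp("dicrotic_notch_depth must be in [0, 0.5]")
  tu <- pressure_upstroke_delay + severity_decoupling
  if (tu + pressure_rise_time >= T)
    stop_vp("pressure upstroke (%.3f + %.3f s) does not fit in the cycle (%.3f s)",
            tu, pressure_rise_time, T)
  if (ejection_onset_delay + ejection_duration >= T)
    stop_vp("ejection does not fit in the cycle")
  structure(p, class = "beat_params")
}

# closed-form aortic pressure at cardiac phase phi in [0, T)
pressure_wave <- function(phi, p) {
  T <- 60 / p$heart_rate
  tu <- p$pressure_upstroke_delay + p$severity_decoupling
  Tr <- p$pressure_rise_time
  tau <- p$diastolic_decay_tau
  E <- exp(-(T - Tr) / tau)
  P_inf <- (p$Pdia - p$Psys * E) / (1 - E)  # decay asymptote so min == Pdia
  decay <- function(e) P_inf + (p$Psys - P_inf) * exp(-e / tau)
  out <- numeric(length(phi))
  pre <- phi < tu
  rise <- phi >= tu & phi < tu + Tr
  post <- phi >= tu + Tr
  out[pre] <- decay(phi[pre] + T - tu - Tr)
  out[rise] <- p$Pdia + (p$Psys - p$Pdia) * (1 - cos(pi * (phi[rise] - tu) / Tr)) / 2
  out[post] <- decay(phi[post] - tu - Tr)
  t_notch <- tu + Tr + 0.03
  out - p$dicrotic_notch_depth * (p$Psys - p$Pdia) *
    exp(-((phi - t_notch) / 0.02)^2)
}

# closed-form LVOT velocity envelope at cardiac phase phi in [0, T)
velocity_wave <- function(phi, p) {
  d0 <- p$ejection_onset_delay
  Ta <- p$acceleration_time
  Te <- p$ejection_duration
  out <- numeric(length(phi))
  up <- phi >= d0 & phi <= d0 + Ta
  down <- phi > d0 + Ta & phi <= d0 + Te
  out[up] <- p$Vpeak * (1 - cos(pi * (phi[up] - d0) / Ta)) / 2
  out[down] <- p$Vpeak * (1 + cos(pi * (phi[down] - d0 - Ta) / (Te - Ta))) / 2
  out
}

#' Generate a paired pressure/velocity recording with known landmarks
#'
#' Samples the closed-form pressure and velocity waveforms of
#' [beat_params()] over `n_beats` identical cardiac cycles at `rate` Hz,
#' with R-peaks annotated at every cycle start and optional additive
#' Gaussian noise, and returns the analytic landmark values alongside.  The
#' ground truth (`truth`) is evaluated on a 0.05 ms grid of the noiseless
#' closed forms, independent of the sampling/meshing pipeline under test.
#'
#' @param params A [beat_params()] list.
#' @param noise_sd Additive Gaussian noise SD, in each channel's units
#'   (default 0).
#' @param seed Integer seed for the noise (optional).
#' @param n_beats Number of cycles (default 22, so that 20 full beats remain
#'   after discarding the partial tail).
#' @param rate Sampling rate, Hz (default 250).
#' @return List with `pressure` and `velocity` [sampled_trace()]s (R-peaks
#'   annotated), `truth` (Vmax, t_Vmax, Vo, P_Vo, P_Vmax, Pmax, slope_index,
#'   alpha_deg) and `params`.
#' @export
gen_beat_pair <- function(params, noise_sd = 0, seed = NULL,
                          n_beats = 22, rate = 250) {
  stopifnot(inherits(params, "beat_params"))
  if (noise_sd < 0) stop_vp("noise_sd must be non-negative")
  T <- 60 / params$heart_rate
  n_samp <- ceiling(n_beats * T * rate) + 1L
  times <- seq(0, by = 1 / rate, length.out = n_samp)
  phi <- times %% T
  pv <- pressure_wave(phi, params)
  vv <- velocity_wave(phi, params)
  if (noise_sd > 0) {
    noise <- with_seed(seed, list(p = stats::rnorm(n_samp, 0, noise_sd),
                                  v = stats::rnorm(n_samp, 0, noise_sd)))
    pv <- pmax(pv + noise$p, 1e-6)
    vv <- pmax(vv + noise$v, 0)
  }
  r <- seq(0, n_beats * T, by = T)
  r <- r[r <= times[n_samp]]
  fine <- seq(0, T, by = 5e-5)
  pfine <- pressure_wave(fine, params)
  t_vmax <- params$ejection_onset_delay + params$acceleration_time
  p_vo <- min(pfine)
  p_vmax <- pressure_wave(t_vmax, params)
  vo_t <- params$ejection_onset_delay
  truth <- list(Vmax = params$Vpeak, t_Vmax = t_vmax, Vo = 0, t_Vo = vo_t,
                P_Vo = p_vo, P_Vmax = p_vmax, Pmax = max(pfine),
                slope_index = (p_vmax - p_vo) / params$Vpeak,
                alpha_deg = atan((p_vmax - p_vo) / params$Vpeak) * 180 / pi)
  list(pressure = sampled_trace(times, pv, "pressure", r_peaks = r),
       velocity = sampled_trace(times, vv, "velocity", r_peaks = r),
       truth = truth, params = params)
}

#' Full waveform-to-features pipeline
#'
#' Convenience wrapper chaining [segment_beats()], [mesh_beat()],
#' [average_beats()], [build_loop()], [extract_landmarks()] and
#' [compute_features()] on one paired recording.
#'
#' @param pressure,velocity [sampled_trace()]s with R-peak annotations.
#' @param n_points Mesh size per beat (default 256).
#' @param vo_frac Ejection-onset threshold for Vo (default 0.05).
#' @return A `vp_features` object; the loop itself is attached as
#'   `attr(, "loop")`.
#' @export
extract_features <- function(pressure, velocity, n_points = 256, vo_frac = 0.05) {
  avg <- function(tr) average_beats(lapply(segment_beats(tr), mesh_beat,
                                           n_points = n_points))
  loop <- build_loop(avg(pressure), avg(velocity))
  feats <- compute_features(extract_landmarks(loop, vo_frac = vo_frac))
  attr(feats, "loop") <- loop
  feats
}
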