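# shared fixture builders (everything is generated in code; no data files)

# a physiologically plausible random parameter set for the beat generator,
# constrained so the waveform components fit inside one cycle
random_beat_params <- function() {
  hr <- runif(1, 60, 85)
  repeat {
    ta <- runif(1, 0.10, 0.18)
    te <- runif(1, 0.28, 0.36)
    if (ta < te - 0.05) break
  }
  beat_params(
    heart_rate = hr,
    Pdia = runif(1, 60, 80),
    Psys = runif(1, 110, 160),
    pressure_upstroke_delay = runif(1, 0.06, 0.10),
    pressure_rise_time = runif(1, 0.20, 0.30),
    dicrotic_notch_depth = runif(1, 0.05, 0.15),
    diastolic_decay_tau = runif(1, 0.4, 0.7),
    Vpeak = runif(1, 60, 100),
    ejection_onset_delay = runif(1, 0.03, 0.07),
    ejection_duration = te,
    acceleration_time = ta,
    severity_decoupling = runif(1, 0, 0.05)
  )
}

# random landmark sets with the orderings the landmark extractor guarantees
random_landmarks <- function() {
  p_vo <- runif(1, 50, 90)
  pmax <- p_vo + runif(1, 20, 90)
  p_vmax <- runif(1, p_vo, pmax + 20)
  vmax <- runif(1, 40, 120)
  list(Vmax = vmax, t_Vmax = runif(1, 0.1, 0.3),
       Vo = runif(1, 0, 0.05 * vmax), t_Vo = runif(1, 0.02, 0.08),
       P_Vo = p_vo, P_Vmax = p_vmax, Pmax = pmax,
       t_Pmax = runif(1, 0.2, 0.4), V_Pmax = runif(1, 0, vmax))
}

# a patient record with every field present (override what the test needs)
toy_record <- function(...) {
  rec <- list(id = "T1",
              smwt_base = 300, smwt_30d = 340, smwt_6m = 340,
              ntprobnp_base = 4000, ntprobnp_30d = 1500, ntprobnp_6m = 1500,
              nyha_pre = 3, nyha_post = 2, kccq_pre = 40, kccq_post = 60,
              death_time = NA_real_, death_cause = "none",
              hf_event_after_30d = FALSE,
              survival_time_2y = 730, survival_status = "alive")
  utils::modifyList(rec, list(...))
}

# triangular-velocity / linear-pressure loop with a closed-form answer
piecewise_linear_loop <- function(n = 301) {
  mesh <- seq(0, 0.30, length.out = n)
  vel <- ifelse(mesh <= 0.10, 1000 * mesh, 100 - 500 * (mesh - 0.10))
  pres <- 70 + 50 * mesh / 0.30
  structure(list(mesh = mesh, velocity = vel, pressure = pres),
            class = "vp_loop")
}
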