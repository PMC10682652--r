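test_that("build_loop pairs matching meshes and rejects mismatches", {
  sim <- gen_beat_pair(beat_params())
  pavg <- average_beats(lapply(segment_beats(sim$pressure), mesh_beat))
  vavg <- average_beats(lapply(segment_beats(sim$velocity), mesh_beat))
  loop <- build_loop(pavg, vavg)
  expect_s3_class(loop, "vp_loop")
  expect_length(loop$mesh, 256)

  vavg128 <- average_beats(lapply(segment_beats(sim$velocity), mesh_beat,
                                  n_points = 128))
  expect_error(build_loop(pavg, vavg128), "mesh lengths differ")

  short <- vavg
  short$mesh <- vavg$mesh * 0.85          # 15% duration mismatch
  expect_error(build_loop(pavg, short), "10%")
})

test_that("loop traversal reproduces the generator's parametric curve", {
  sim <- gen_beat_pair(beat_params())
  pavg <- average_beats(lapply(segment_beats(sim$pressure), mesh_beat))
  vavg <- average_beats(lapply(segment_beats(sim$velocity), mesh_beat))
  loop <- build_loop(pavg, vavg)
  p_true <- vploop:::pressure_wave(loop$mesh, sim$params)
  v_true <- vploop:::velocity_wave(loop$mesh, sim$params)
  expect_lt(max(abs(loop$pressure - p_true)), 0.5)   # mmHg
  expect_lt(max(abs(loop$velocity - v_true)), 1.0)   # cm/s
})

test_that("landmarks match the piecewise-linear closed form", {
  lm <- extract_landmarks(piecewise_linear_loop())
  expect_equal(lm$Vmax, 100, tolerance = 1e-10)
  expect_equal(lm$t_Vmax, 0.10, tolerance = 1e-10)
  expect_equal(lm$P_Vo, 70, tolerance = 1e-10)
  expect_equal(lm$P_Vmax, 70 + 50 * (0.10 / 0.30), tolerance = 1e-6)
  expect_equal(lm$Pmax, 120, tolerance = 1e-10)
})

test_that("landmark degenerate and tie-break rules", {
  const_p <- structure(list(mesh = seq(0, 0.3, length.out = 31),
                            velocity = c(seq(0, 60, length.out = 16),
                                         seq(56, 0, length.out = 15)),
                            pressure = rep(90, 31)), class = "vp_loop")
  lm <- extract_landmarks(const_p)
  expect_equal(lm$P_Vo, 90)
  expect_equal(lm$P_Vmax, 90)
  expect_equal(lm$Pmax, 90)
  expect_equal(compute_features(lm)$dP_ejection, 0)

  zero <- const_p; zero$velocity <- rep(0, 31)
  expect_error(extract_landmarks(zero), "degenerate")

  # two equal velocity maxima: the first wins
  twin <- const_p
  twin$velocity <- c(rep(0, 5), 50, rep(10, 10), 50, rep(0, 14))
  expect_equal(extract_landmarks(twin)$t_Vmax, const_p$mesh[6])
})

test_that("feature formulas follow the arctangent closed forms", {
  lm <- random_landmarks()
  lm$P_Vmax <- lm$P_Vo + 10; lm$Vmax <- 100
  f <- compute_features(lm)
  expect_equal(f$slope_index, 0.1, tolerance = 1e-12)
  expect_equal(f$alpha_deg, 5.7106, tolerance = 1e-4)

  lm$P_Vmax <- lm$P_Vo
  expect_equal(compute_features(lm)$alpha_deg, 0)

  # the group-level pairing: ALPHA 4.21 deg corresponds to ratio tan(4.21 deg)
  expect_equal(tan(4.21 * pi / 180), 0.0736, tolerance = 1e-3)

  lm$Vmax <- 0
  expect_error(compute_features(lm), "positive")
})

test_that("tan(ALPHA) is identically the slope index and behaves under transforms", {
  set.seed(99)
  for (i in 1:200) {
    lm <- random_landmarks()
    f <- compute_features(lm)
    expect_equal(tan(f$alpha_deg * pi / 180), f$slope_index, tolerance = 1e-9)
    expect_equal(f$dP_ejection, f$slope_index * lm$Vmax, tolerance = 1e-9)
    expect_true(f$alpha_deg >= -90 && f$alpha_deg <= 90)
    expect_true(f$beta_deg >= -90 && f$beta_deg <= 90 + 1e-12)
    expect_true(f$gala_deg >= 0 && f$gala_deg <= 90 + 1e-12)

    # additive pressure shift leaves the index unchanged
    sh <- lm; for (k in c("P_Vo", "P_Vmax", "Pmax")) sh[[k]] <- sh[[k]] + 25
    expect_equal(compute_features(sh)$slope_index, f$slope_index, tolerance = 1e-12)

    # velocity scaling by c scales the index by 1/c
    sc <- lm; sc$Vmax <- lm$Vmax * 4; sc$V_Pmax <- lm$V_Pmax * 4; sc$Vo <- lm$Vo * 4
    expect_equal(compute_features(sc)$slope_index, f$slope_index / 4,
                 tolerance = 1e-12)
  }
})

test_that("R-wave-timed pressure lookup interpolates linearly", {
  tt <- seq(0, 0.5, by = 0.01)
  tr <- sampled_trace(tt, 70 + 100 * tt, "pressure", r_peaks = 0)
  expect_equal(pressure_at_vmax_by_rwave(tr, 0.1), 80)
  expect_equal(pressure_at_vmax_by_rwave(tr, 0), 70)

  tr2 <- sampled_trace(seq(0, 2.4, by = 0.01), rep(90, 241), "pressure",
                       r_peaks = c(0, 1, 2))
  expect_error(pressure_at_vmax_by_rwave(tr2, 1.2), "R-R")
})

test_that("feature export carries units in key names", {
  f <- compute_features(extract_landmarks(piecewise_linear_loop()))
  l <- as.list(f)
  expect_named(l, c("alpha_deg", "beta_deg", "gala_deg",
                    "slope_index_mmHg_per_cm_s", "dP_ejection_mmHg",
                    "late_rise_mmHg", "Vmax_cm_s", "t_Vmax_s", "Vo_cm_s",
                    "t_Vo_s", "P_Vo_mmHg", "P_Vmax_mmHg", "Pmax_mmHg",
                    "t_Pmax_s", "V_Pmax_cm_s"))
})
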