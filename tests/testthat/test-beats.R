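test_that("segmentation yields one beat per R-R interval, relative to the R-peak", {
  t <- seq(0, 20.996, by = 0.004)
  tr <- sampled_trace(t, 80 + 10 * sin(2 * pi * t), "pressure",
                      r_peaks = seq(0, 20, by = 1))
  beats <- segment_beats(tr)
  expect_length(beats, 20)                       # 21 R-peaks -> 20 intervals
  expect_true(all(vapply(beats, function(b) b$rel_times[1] == 0, logical(1))))

  t2 <- seq(0, 1.2, by = 0.01)
  tr2 <- sampled_trace(t2, rep(90, length(t2)), "pressure", r_peaks = c(0, 1))
  b2 <- segment_beats(tr2)
  expect_length(b2, 1)
  expect_equal(b2[[1]]$rel_times, seq(0, 0.99, by = 0.01))

  expect_error(segment_beats(sampled_trace(t2, rep(90, length(t2)), "pressure")),
               "2 R-peaks")
})

test_that("segmented beats match the generator's per-beat template", {
  sim <- gen_beat_pair(beat_params(), n_beats = 25)
  T <- 60 / sim$params$heart_rate
  for (b in segment_beats(sim$velocity)) {
    truth <- vploop:::velocity_wave(b$rel_times %% T, sim$params)
    expect_equal(b$values, truth, tolerance = 1e-8)
  }
})

test_that("meshing is exact on linear data and preserves endpoints", {
  ramp <- vp_beat("velocity", seq(0, 1, length.out = 21), seq(0, 10, length.out = 21))
  m <- mesh_beat(ramp, 101)
  expect_equal(m$values, seq(0, 10, length.out = 101))

  const <- vp_beat("pressure", seq(0, 1, length.out = 16), rep(7, 16))
  expect_true(all(mesh_beat(const, 64)$values == 7))

  expect_error(mesh_beat(ramp, 15), "at least 16")

  # endpoints preserved exactly on irregular sampling
  tt <- c(0, sort(runif(40, 0.001, 0.799)), 0.8)
  irr <- vp_beat("pressure", tt, 70 + 30 * sin(pi * tt / 0.8))
  mm <- mesh_beat(irr, 256)
  expect_identical(mm$values[1], irr$values[1])
  expect_identical(mm$values[256], irr$values[length(tt)])
})

test_that("mesh refinement converges: N=64 vs N=1024 on a half-sine beat", {
  tt <- seq(0, 0.8, by = 1 / 250)
  halfsine <- vp_beat("velocity", tt, 100 * sin(pi * tt / 0.8))
  coarse <- mesh_beat(halfsine, 64)
  fine <- mesh_beat(halfsine, 1024)
  back <- approx(coarse$mesh, coarse$values, xout = fine$mesh)$y
  expect_lt(max(abs(back - fine$values)) / 100, 1e-3)
})

test_that("beat averaging is idempotent, symmetric and order-invariant", {
  tt <- seq(0, 0.8, by = 1 / 250)
  b <- mesh_beat(vp_beat("velocity", tt, 50 * sin(pi * tt / 0.8)^2), 128)
  expect_equal(suppressWarnings(average_beats(list(b, b)))$values, b$values)

  v <- 50 * sin(pi * tt / 0.8)^2
  b1 <- mesh_beat(vp_beat("velocity", tt, v), 128)
  b2 <- mesh_beat(vp_beat("velocity", tt, -v + 2 * 30), 128)
  expect_equal(suppressWarnings(average_beats(list(b1, b2)))$values,
               rep(30, 128))

  set.seed(5)
  beats <- lapply(1:20, function(i)
    mesh_beat(vp_beat("pressure", tt, 80 + v + rnorm(length(tt))), 128))
  expect_equal(average_beats(beats)$values,
               average_beats(rev(beats))$values)

  pb <- mesh_beat(vp_beat("pressure", tt, 80 + v), 128)
  expect_error(average_beats(list(b1, pb)), "mixed channels")
  expect_warning(average_beats(list(b1, b1, b1)), "fewer")
})

test_that("averaging 20 noisy beats suppresses noise as 1/sqrt(20)", {
  tt <- seq(0, 0.8, by = 1 / 250)
  tmpl <- 90 + 30 * sin(pi * tt / 0.8)^2
  sigma <- 2
  ratios <- sapply(1:5, function(s) {
    set.seed(s)
    beats <- lapply(1:20, function(i)
      mesh_beat(vp_beat("pressure", tt, tmpl + rnorm(length(tt), 0, sigma)), 256))
    avg <- average_beats(beats)
    tmpl_mesh <- approx(tt, tmpl, xout = avg$mesh)$y
    sqrt(mean((avg$values - tmpl_mesh)^2)) / (sigma / sqrt(20))
  })
  expect_true(all(ratios > 1 / 1.5 & ratios < 1.5))
})

test_that("segment -> mesh -> average reproduces the noiseless template", {
  sim <- gen_beat_pair(beat_params())
  for (ch in c("pressure", "velocity")) {
    avg <- average_beats(lapply(segment_beats(sim[[ch]]), mesh_beat))
    truth <- if (ch == "pressure")
      vploop:::pressure_wave(avg$mesh, sim$params)
    else vploop:::velocity_wave(avg$mesh, sim$params)
    amp <- diff(range(truth))
    expect_lt(max(abs(avg$values - truth)) / amp, 0.01)
  }
})
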