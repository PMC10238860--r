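test_that("conservation and flow-pressure consistency hold at machine precision", {
  for (g in c(0, 0.3, 0.48)) {
    b <- simulate_beat(sim_params(gamma = g))
    zc <- b$truth$zc_true
    expect_lt(max(abs(b$p - b$truth$dbp_mmhg - b$pf_true - b$pb_true)), 1e-10)
    expect_lt(max(abs(b$q - (b$pf_true - b$pb_true) / zc)), 1e-9)
    expect_lt(max(abs((b$p - b$truth$dbp_mmhg - 2 * b$pb_true) - zc * b$q)), 1e-9)
  }
  ## reflectionless identity: p - dbp = zc * q pointwise
  b0 <- simulate_beat(sim_params(gamma = 0))
  expect_true(all(b0$pb_true == 0))
  expect_lt(max(abs(b0$p - b0$truth$dbp_mmhg - b0$truth$zc_true * b0$q)), 1e-10)
})

test_that("backward/forward amplitude ratio equals gamma and grows with it", {
  b <- simulate_beat(sim_params(gamma = 0.48))
  ratio <- (max(b$pb_true) - min(b$pb_true)) / (max(b$pf_true) - min(b$pf_true))
  expect_equal(ratio, 0.48, tolerance = 1e-12)

  amps <- sapply(seq(0.1, 0.8, 0.1), function(g) {
    bb <- simulate_beat(sim_params(gamma = g))
    max(bb$pb_true) - min(bb$pb_true)
  })
  expect_true(all(diff(amps) > 0))
})

test_that("positive-flow integral recovers the requested stroke volume", {
  for (fs in c(250, 500)) {
    b <- simulate_beat(hf_preset("baseline", seed = 1, fs_hz = fs,
                                 noise_sd_mmhg = 0, noise_sd_flow = 0))
    sv <- trapz(b$t, pmax(b$q, 0))
    expect_equal(sv, 41.2, tolerance = 0.01)
  }
})

test_that("recordings are reproducible for a fixed seed and sized by rate", {
  p <- sim_params(seed = 99, noise_sd_mmhg = 0.5, noise_sd_flow = 2)
  r1 <- simulate_recording(p, 16)
  r2 <- simulate_recording(p, 16)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$q, r2$q)

  r <- simulate_recording(sim_params(hr_bpm = 86.5, seed = 5), 40)
  expected <- 40 * (60 / 86.5) * 500
  expect_lt(abs(length(r$p) - expected) / expected, 0.05)

  ## cross-module oracle: beat detection recovers the generated onsets
  p0 <- sim_params(gamma = 0.45, tau_ms = 60, seed = 2)
  rec <- simulate_recording(p0, 8, jitter_frac = 0)
  pfil <- filter_pressure(rec$p, 500)
  beats <- detect_beats(pfil, 500)
  expect_equal(nrow(beats), 8)
  expect_true(all(abs(beats$onset_idx - attr(rec, "truth")$beat_starts) <= 2))
})

test_that("invalid parameters raise errors naming the offending field", {
  expect_error(sim_params(gamma = 1.2), "gamma")
  expect_error(sim_params(gamma = -0.1), "gamma")
  expect_error(sim_params(ed_ms = 800, hr_bpm = 86.5), "ed_ms")
  expect_error(sim_params(tau_ms = 300, ed_ms = 230), "tau_ms")
  expect_error(sim_params(sv_ml = -5), "sv_ml")
  expect_error(sim_params(fs_hz = 0), "fs_hz")
  expect_error(simulate_recording(sim_params(), 0), "n_beats")
})

test_that("heart-failure presets carry the study-arm parameters", {
  m1 <- hf_preset("month1")
  expect_equal(m1$hr_bpm, 120.9)
  expect_equal(m1$sv_ml, 20.8)
  w1 <- hf_preset("week1")
  expect_equal(w1$hr_bpm, 99.1)
  expect_equal(w1$sv_ml, 28.0)
  bl <- hf_preset("baseline")
  expect_equal(bl$gamma, 0.48)
  expect_equal(bl$sv_ml, 41.2)
  ## characteristic impedance unchanged by pacing
  expect_identical(bl$zc_true, m1$zc_true)
  expect_identical(bl$zc_true, w1$zc_true)
  ## reflection magnitude declines across stages
  expect_true(bl$gamma > w1$gamma && w1$gamma >= m1$gamma)
  expect_error(hf_preset("month2"), "baseline.*week1.*month1")
})
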