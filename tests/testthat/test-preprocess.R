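test_that("pressure filter preserves DC and passband, attenuates high frequency", {
  fs <- 500
  t <- (0:(6 * fs - 1)) / fs
  expect_equal(filter_pressure(rep(90, length(t)), fs), rep(90, length(t)),
               tolerance = 1e-9)

  mid <- seq(fs, 5 * fs)  # avoid edges when measuring gain
  s2 <- sin(2 * pi * 2 * t)
  gain2 <- sd(filter_pressure(s2, fs)[mid]) / sd(s2[mid])
  expect_gt(gain2, 0.95)

  s50 <- sin(2 * pi * 50 * t)
  gain50 <- sd(filter_pressure(s50, fs)[mid]) / sd(s50[mid])
  expect_lt(gain50, 0.10)

  ## zero phase: the peak of a symmetric pulse does not move
  pulse <- 80 + 40 * exp(-((t - 3) / 0.05)^2)
  expect_equal(which.max(filter_pressure(pulse, fs)), which.max(pulse))

  expect_error(filter_pressure(rnorm(10), fs), "too short")
})

test_that("beat detection finds every simulated onset and survives artifacts", {
  p0 <- sim_params(gamma = 0.45, tau_ms = 60, seed = 2)
  rec <- simulate_recording(p0, 8, jitter_frac = 0)
  pfil <- filter_pressure(rec$p, 500)
  beats <- detect_beats(pfil, 500)
  expect_equal(nrow(beats), 8)
  expect_true(all(abs(beats$onset_idx - attr(rec, "truth")$beat_starts) <= 2))
  expect_true(all(beats$onset_idx < beats$sys_peak_idx &
                  beats$sys_peak_idx < beats$end_idx))
  ## translation invariance: prepending k flat samples shifts all indices by k
  k <- 40
  shifted <- detect_beats(c(rep(pfil[1], k), pfil), 500)
  expect_equal(shifted$sys_peak_idx, beats$sys_peak_idx + k)

  ## a 5-sample spike 30 mmHg above SBP does not add a beat
  spiky <- rec$p
  i <- attr(rec, "truth")$beat_starts[4] + 260
  spiky[i:(i + 4)] <- max(rec$p) + 30
  beats2 <- detect_beats(filter_pressure(spiky, 500), 500)
  expect_equal(nrow(beats2), nrow(beats))

  expect_error(detect_beats(rep(80, 1000), 500), "detection error")
})

test_that("ensemble averaging groups, normalizes and maps back to members", {
  p0 <- sim_params(gamma = 0.45, tau_ms = 60, seed = 2)
  rec <- simulate_recording(p0, 16, jitter_frac = 0)
  ## segments from generative truth: 16 bitwise-identical noise-free members
  pfil <- rec$p
  starts <- attr(rec, "truth")$beat_starts
  beats <- data.frame(onset_idx = starts,
                      sys_peak_idx = starts + 50L,
                      end_idx = c(starts[-1], length(rec$p)))
  class(beats) <- c("pw_beats", "data.frame")
  expect_length(ensemble_average(beats, pfil), 2)
  expect_length(ensemble_average(beats[1:15, ], pfil), 1)
  expect_error(ensemble_average(beats[1:5, ], pfil), "grouping error")

  e <- ensemble_average(beats, pfil)[[1]]
  expect_equal(min(e$fn), 0, tolerance = 1e-9)
  expect_equal(max(e$fn), 1, tolerance = 1e-9)
  ## jitter-free identical beats: fn equals any normalized member
  j <- 1
  seg <- pfil[e$members$onset_idx[j]:e$members$end_idx[j]]
  y <- approx(seq(0, 1, length.out = length(seg)), seg,
              seq(0, 1, length.out = 500))$y
  y <- (y - min(y)) / (max(y) - min(y))
  expect_lt(max(abs(e$fn - y)), 1e-6)
  ## landmark mapping inverts the stated resampling
  for (k in c(1, 137, 366, 500)) {
    len <- e$member_len[3]
    expect_equal(landmark_to_member(e, k, 3),
                 e$members$onset_idx[3] + round((k - 1) * (len - 1) / 499))
  }
})

test_that("derivative chain matches closed forms on analytic inputs", {
  n <- 500
  t <- seq(0, 1, length.out = n)
  ramp <- 2.5 * t
  d <- derivative_chain(ramp, dx = 1)
  expect_equal(d$d1, rep(2.5 / (n - 1), n), tolerance = 1e-9)
  for (k in 2:5) expect_lt(max(abs(d[[k]])), 1e-6 * 2.5 / (n - 1))

  s <- sin(2 * pi * t)
  d <- derivative_chain(s)
  core <- 30:(n - 30)
  expect_lt(max(abs(d$d2[core] + (2 * pi)^2 * s[core])) / (2 * pi)^2, 0.01)

  cubic <- 1 + t - 0.5 * t^2 + 2 * t^3
  d <- derivative_chain(cubic, dx = 1)
  expect_lt(max(abs(d$d4[core])), 1e-8)
  expect_lt(max(abs(d$d5[core])), 1e-8)

  expect_error(derivative_chain(1:5), "length error")
})
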