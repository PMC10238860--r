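## a clean beat with mapped landmarks and lightly smoothed pressure, the way
## the pipeline hands beats to the synthesis step
synth_fixture <- function(gamma = 0.48, tau_ms = 100, seed = 5, ...) {
  params <- sim_params(gamma = gamma, tau_ms = tau_ms, frac_tp = 0.43,
                       seed = seed, ...)
  fix <- ens_with_landmarks(params)
  mb <- member_landmarks(fix, 1)
  pw <- signal::sgolayfilt(fix$rec$p, p = 2, n = 23)
  list(params = params, p = pw[mb$seg_idx], q = fix$rec$q[mb$seg_idx],
       lm = mb$lm)
}

test_that("synthetic flow is zero at the notch and reverses before the rebound", {
  fx <- synth_fixture()
  sf <- synthesize_flow(fx$p, fx$lm, 500)
  expect_identical(sf$qs[sf$dn_idx], 0)
  expect_true(all(sf$qs[(sf$dpeak_idx + 1):length(sf$qs)] == 0))
  imin <- which.min(sf$qs)
  expect_gt(imin, sf$dn_idx)
  expect_lte(imin, sf$dpeak_idx)
  expect_lt(min(sf$qs), 0)
})

test_that("synthetic flow is shape-concordant with measured flow in systole", {
  fx <- synth_fixture()
  sf <- synthesize_flow(fx$p, fx$lm, 500)
  rho <- spearman_rho(sf$qs[1:sf$dn_idx], fx$q[1:sf$dn_idx])
  expect_gte(rho, 0.90)
})

test_that("every retained index is invariant to the synthetic flow scale", {
  fx <- synth_fixture()
  sf <- synthesize_flow(fx$p, fx$lm, 500)
  r1 <- wsa_wpa_from_synthetic(fx$p, sf$qs, fx$lm, 500)
  r2 <- wsa_wpa_from_synthetic(fx$p, sf$qs * 57.3, fx$lm, 500)
  for (nm in c("rm", "pf_amp", "pb_amp", "qzc_int", "wasted_effort",
               "wasted_ratio", "fcw_few_ratio"))
    expect_equal(r1[[nm]], r2[[nm]], tolerance = 1e-9, label = nm)
})

test_that("a perfectly proportional synthetic flow reproduces measured RM", {
  fx <- synth_fixture()
  fit <- estimate_zc(fx$p, fx$q, 500)
  rm_meas <- separate_waves(fx$p, fx$q, fit$zc)$rm
  rm_syn <- wsa_wpa_from_synthetic(fx$p, fx$q * 0.0123, fx$lm, 500)$rm
  expect_equal(rm_syn, rm_meas, tolerance = 1e-9)
})

test_that("uncalibrated results suppress absolute impedance and wave heights", {
  fx <- synth_fixture()
  sf <- synthesize_flow(fx$p, fx$lm, 500)
  res <- wsa_wpa_from_synthetic(fx$p, sf, fx$lm, 500)
  expect_false(any(c("zc", "fcw_height", "few_height") %in% names(res)))
  expect_identical(res$flow_source, "synthetic")
})

test_that("synthesis refuses beats without the required landmarks", {
  fx <- synth_fixture()
  bad <- fx$lm; bad$dn <- NA_integer_
  expect_error(synthesize_flow(fx$p, bad, 500), "synthesis error")
  bad2 <- fx$lm; bad2$p1 <- NA_integer_; bad2$augmentation <- "positive"
  expect_error(synthesize_flow(fx$p, bad2, 500), "synthesis error")
  ## monotone decay after the notch: no diastolic rebound to anchor on
  p_mono <- c(seq(0, 40, length.out = 100), seq(40, 0.5, length.out = 200))
  lm <- list(p1 = 60, p2 = NA_integer_, dn = 150, augmentation = "positive")
  expect_error(synthesize_flow(p_mono, lm, 500), "synthesis error")
})

test_that("measured-synthetic agreement degrades with pressure noise", {
  widths <- sapply(c(0.5, 2, 6), function(nsd) {
    rec <- simulate_recording(sim_params(gamma = 0.45, tau_ms = 70,
                                         noise_sd_mmhg = nsd,
                                         noise_sd_flow = 2, seed = 41), 24)
    res <- analyze_recording(rec)
    mg <- merge(res$per_beat$measured, res$per_beat$synthetic,
                by = c("group", "beat"), suffixes = c("_m", "_s"))
    ba <- bland_altman(mg$rm_m, mg$rm_s)
    ba$loa_high - ba$loa_low
  })
  expect_true(all(diff(widths) > 0))
})
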