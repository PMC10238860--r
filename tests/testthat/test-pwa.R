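test_that("triangle pulse reproduces closed-form areas and identities", {
  fs <- 1000
  p <- c(seq(80, 120, length.out = 101), seq(120, 95, length.out = 201)[-1])
  lm <- list(p1 = 101, p2 = NA_integer_, dn = 301, augmentation = "negative")
  ix <- compute_pwa_indices(p, lm, fs)
  expect_equal(ix$psa, 7500)
  expect_equal(ix$delta_spti, 24000)
  expect_equal(ix$ew, 0)
  expect_equal(ix$ed_ms, 300)
  expect_equal(ix$ed_ms, ix$tr_ms + ix$sdr_ms, tolerance = 1e-9)
  expect_equal(ix$spti, ix$delta_spti + ix$psa + ix$ew, tolerance = 1e-9)
})

test_that("positive-augmentation landmarks match the reflection geometry", {
  fix <- ens_with_landmarks(sim_params(gamma = 0.45, tau_ms = 60,
                                       frac_tp = 0.43, seed = 1))
  lk <- fix$lmk
  expect_true(lk$valid)
  expect_identical(lk$augmentation, "positive")
  expect_lt(lk$p1_idx, lk$p2_idx)
  expect_lt(lk$p2_idx, lk$dn_idx)

  ## P1 maps onto a fourth-derivative down-crossing of the un-resampled
  ## member beat found by an independent wide-stencil oracle
  mb <- member_landmarks(fix, 1)
  oracle <- oracle_d4_down_crossings(fix$pfil[mb$seg_idx])
  expect_lte(min(abs(oracle - mb$lm$p1)), 3)

  ## round-trip reflection time tracks the generative delay
  ix <- compute_pwa_indices(fix$pfil[mb$seg_idx], mb$lm, 500)
  expect_lt(abs(ix$tr_ms - 60), 10)
  expect_equal(ix$ed_ms, ix$tr_ms + ix$sdr_ms, tolerance = 1e-6)
  expect_equal(ix$spti, ix$delta_spti + ix$psa + ix$ew,
               tolerance = 1e-6 * ix$spti)
})

test_that("reflectionless beats take the negative-augmentation branch", {
  fix <- ens_with_landmarks(sim_params(gamma = 0, tau_ms = 60,
                                       frac_tp = 0.43, seed = 1))
  expect_true(fix$lmk$valid)
  expect_identical(fix$lmk$augmentation, "negative")
  expect_equal(fix$lmk$p1_idx, which.max(fix$ens$fn))
})

test_that("the dicrotic notch lands in the generated incisura window", {
  params <- sim_params(gamma = 0.45, tau_ms = 60, frac_tp = 0.43, seed = 1)
  fix <- ens_with_landmarks(params)
  ms_per_idx <- (fix$ens$mean_len / 500) / (fix$ens$n_out - 1) * 1000
  dn_ms <- (fix$lmk$dn_idx - 1) * ms_per_idx
  ## window start/end with a tolerance for the low-pass transition width
  expect_gte(dn_ms, params$ed_ms - 10)
  expect_lte(dn_ms, params$ed_ms + params$inc_width_ms + 10)
})

test_that("areas scale linearly with pressure and identities survive scaling", {
  fix <- ens_with_landmarks(sim_params(gamma = 0.45, tau_ms = 60,
                                       frac_tp = 0.43, seed = 4))
  mb <- member_landmarks(fix, 2)
  p_seg <- fix$pfil[mb$seg_idx]
  a <- compute_pwa_indices(p_seg, mb$lm, 500)
  k <- 1.73
  b <- compute_pwa_indices(k * p_seg, mb$lm, 500)
  for (nm in c("psa", "spti", "delta_spti", "dpti", "ew", "ap"))
    expect_equal(b[[nm]], k * a[[nm]], tolerance = 1e-9,
                 label = sprintf("%s scales", nm))
  for (nm in c("ed_ms", "tr_ms", "sdr_ms"))
    expect_identical(b[[nm]], a[[nm]])
})

test_that("session aggregation averages valid beats and flags exclusions", {
  rows <- do.call(rbind, list(
    data.frame(psa = 7000, ed_ms = 230),
    data.frame(psa = 8000, ed_ms = 230)))
  agg <- aggregate_session(rows, n_excluded = 3L)
  expect_equal(unname(agg$mean["psa"]), 7500)
  expect_equal(unname(agg$sd["ed_ms"]), 0)
  expect_equal(agg$n_excluded, 3L)
  expect_error(aggregate_session(rows[0, ]), "aggregation error")

  ## identical beats have zero dispersion on every index
  one <- data.frame(psa = 7500, spti = 30000, dpti = 29000)
  agg2 <- aggregate_session(rbind(one, one, one))
  expect_true(all(agg2$sd == 0))
})

test_that("pulse systolic area tracks stroke volume across beats", {
  psa <- sv <- c()
  for (s in seq(18, 45, length.out = 7)) {
    b <- simulate_beat(sim_params(sv_ml = s, gamma = 0.45, tau_ms = 60,
                                  frac_tp = 0.43))
    dn <- b$truth$inc_window[1] + 7L  # notch from generative truth
    lm <- list(p1 = round(0.3 * dn), p2 = NA_integer_, dn = dn,
               augmentation = "negative")
    psa <- c(psa, compute_pwa_indices(b$p, lm, 500)$psa)
    sv <- c(sv, s)
  }
  expect_gte(spearman_rho(psa, sv), 0.9)
})
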