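## shared fixtures: everything is generated in code at test time

## a clean (noise-free) beat with a well-separated shoulder geometry
clean_beat <- function(gamma = 0.48, tau_ms = 60, frac_tp = 0.43, ...) {
  simulate_beat(sim_params(gamma = gamma, tau_ms = tau_ms, frac_tp = frac_tp, ...))
}

## run the preprocessing chain on a simulated recording and return the first
## ensemble group with its landmarks
ens_with_landmarks <- function(params, n_beats = 8, jitter_frac = 0) {
  rec <- simulate_recording(params, n_beats, jitter_frac = jitter_frac)
  pfil <- filter_pressure(rec$p, params$fs_hz)
  beats <- detect_beats(pfil, params$fs_hz)
  ens <- ensemble_average(beats, pfil, q = rec$q, fs_hz = params$fs_hz)
  list(rec = rec, pfil = pfil, beats = beats, ens = ens[[1]],
       lmk = locate_landmarks(ens[[1]]))
}

## map group landmarks onto member j as local (within-beat) indices
member_landmarks <- function(fix, j = 1) {
  e <- fix$ens
  seg <- e$members$onset_idx[j]:e$members$end_idx[j]
  loc <- function(k) {
    if (is.na(k)) return(NA_integer_)
    min(length(seg), max(1L, landmark_to_member(e, k, j) - e$members$onset_idx[j] + 1L))
  }
  list(seg_idx = seg,
       lm = list(p1 = loc(fix$lmk$p1_idx), p2 = loc(fix$lmk$p2_idx),
                 dn = loc(fix$lmk$dn_idx), peak = loc(fix$lmk$peak_idx),
                 augmentation = fix$lmk$augmentation))
}

## signal-averaged wave separation the way the analysis chain measures it:
## average n noisy repeats of one beat, smooth, fit Zc, separate
recover_rm <- function(gamma, noise_sd, seed, n_avg = 8, tau_ms = 70) {
  ps <- 0; qs <- 0
  for (i in seq_len(n_avg)) {
    b <- simulate_beat(sim_params(gamma = gamma, tau_ms = tau_ms,
                                  noise_sd_mmhg = noise_sd, seed = seed + i))
    ps <- ps + b$p / n_avg
    qs <- qs + b$q / n_avg
  }
  if (noise_sd > 0) {
    ps <- signal::sgolayfilt(ps, p = 2, n = 23)
    qs <- signal::sgolayfilt(qs, p = 2, n = 23)
  }
  fit <- estimate_zc(ps, qs, 500)
  separate_waves(ps, qs, fit$zc)$rm
}

## independent oracle for fourth-derivative down-crossings: a wide-stencil
## central-difference formula applied to an un-resampled waveform
## (structurally different from the package's successive Savitzky-Golay
## chain)
oracle_d4_down_crossings <- function(y, h = 5) {
  n <- length(y)
  i <- (2 * h + 1):(n - 2 * h)
  d4 <- y[i - 2 * h] - 4 * y[i - h] + 6 * y[i] - 4 * y[i + h] + y[i + 2 * h]
  i[which(d4[-length(d4)] > 0 & d4[-1] <= 0)]
}
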