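#' Synthesize an uncalibrated aortic flow waveform from pressure alone
#'
#' Builds a "personalized" flow estimate from a single pressure beat using
#' the pressure-flow concordance principles: (i) up to the inflection point
#' (P1, or P2 for negative-augmentation beats) flow is concordant with
#' diastole-zeroed pressure, so `qs = ps` (the gain is immaterial because
#' flow scaling drops out of every index retained downstream); (ii) from the
#' inflection to the dicrotic notch a quasi-linear reflected-wave ramp `r(t)`
#' rising from 0 at the inflection to `ps(DN)` at the notch is subtracted, so
#' `qs(DN) = 0` exactly at end-ejection; (iii) the ramp is held at `ps(DN)`
#' through the post-notch trough until the first diastolic pressure maximum
#' after the notch, which reproduces the brief early-diastolic flow
#' reversal; (iv) `qs = 0` thereafter. The output is uncalibrated: absolute
#' Zc and absolute wave-power heights are not derivable from it.
#'
#' @param p_beat pressure beat, mmHg (foot at first sample).
#' @param lm list with local indices `p1`, `p2`, `dn` and `augmentation`
#'   (as produced by mapping [locate_landmarks()] onto the beat).
#' @param fs_hz sampling rate.
#' @return A list of class `pw_synth_flow`: `qs` (arbitrary units, same grid
#'   as `p_beat`), `anchor_idx`, `dn_idx`, `dpeak_idx`, `ramp`.
#' @export
synthesize_flow <- function(p_beat, lm, fs_hz) {
  n <- length(p_beat)
  dn <- lm$dn
  anchor <- if (identical(lm$augmentation, "negative")) lm$p2 else lm$p1
  if (is.na(dn) || dn < 2L || dn >= n)
    stop("synthesis error: missing dicrotic notch", call. = FALSE)
  if (is.na(anchor) || anchor < 1L || anchor >= dn)
    stop("synthesis error: missing inflection anchor", call. = FALSE)
  ps <- p_beat - min(p_beat)

  ## The incisura trough sits within ~25 ms of the detected notch and the
  ## diastolic rebound within ~60 ms after the trough; fixed physiologic
  ## windows with an extra light smoothing pass keep the search robust to
  ## both measurement noise and the decaying reflected tail (which can sink
  ## below the trough later in diastole).
  smoothed <- if (n > 13L) signal::sgolayfilt(ps, p = 2, n = 11) else ps
  w_tr <- max(3L, round(0.025 * fs_hz))
  w_pk <- max(3L, round(0.060 * fs_hz))
  dpeak <- NA_integer_
  tr_hi <- min(n, dn + w_tr)
  if (tr_hi > dn + 1L) {
    trough <- dn + which.min(smoothed[(dn + 1L):tr_hi])
    pk_hi <- min(n, trough + w_pk)
    if (pk_hi > trough + 1L) {
      cand <- trough + which.max(smoothed[(trough + 1L):pk_hi])
      pulse <- max(ps) - min(ps)
      if (smoothed[cand] - smoothed[trough] > 0.001 * pulse) dpeak <- cand
    }
  }
  if (is.na(dpeak) || dpeak <= dn)
    stop("synthesis error: no post-notch diastolic pressure maximum", call. = FALSE)

  ramp <- numeric(n)
  seg <- anchor:dn
  ramp[seg] <- ps[dn] * (seg - anchor) / (dn - anchor)
  if (dpeak > dn) ramp[(dn + 1L):dpeak] <- ps[dn]

  qs <- ps - ramp
  if (dpeak < n) qs[(dpeak + 1L):n] <- 0
  structure(list(qs = qs, anchor_idx = anchor, dn_idx = dn,
                 dpeak_idx = dpeak, ramp = ramp),
            class = "pw_synth_flow")
}

#' Flow-scale-invariant WSA/WPA indices from synthetic flow
#'
#' Runs the same early-systolic slope rule on (pressure, synthetic flow) to
#' obtain an effective impedance in synthetic units (near 1 by construction),
#' then wave separation, wasted-effort and wave-power classification.
#' Reported indices are restricted to the flow-scale-invariant subset:
#' forward/backward pressure series and amplitudes, reflection magnitude,
#' QZc integral, wasted effort and its ratio (all pressure-time quantities),
#' and the FCW/FEW height ratio. Absolute Zc and absolute FCW/FEW heights
#' are not derivable from uncalibrated flow and are deliberately absent from
#' the result.
#'
#' @param p_beat pressure beat, mmHg.
#' @param qs synthetic flow from [synthesize_flow()] (the series or the
#'   object).
#' @param lm landmark list as in [synthesize_flow()] (needs `dn` and the
#'   peak-pressure location for wave classification).
#' @param fs_hz sampling rate.
#' @param config a [pw_config()].
#' @return A list of class `pw_synth_result`: `pf`, `pb`, `pf_amp`,
#'   `pb_amp`, `rm`, `qzc_int`, `wasted_effort`, `wasted_ratio`,
#'   `fcw_few_ratio`, `flow_source = "synthetic"`.
#' @export
wsa_wpa_from_synthetic <- function(p_beat, qs, lm, fs_hz,
                                   config = pw_config()) {
  if (inherits(qs, "pw_synth_flow")) qs <- qs$qs
  fit <- estimate_zc(p_beat, qs, fs_hz, config)
  sep <- separate_waves(p_beat, qs, fit$zc)
  we <- wasted_effort_indices(p_beat, qs, fit$zc, lm$dn, fs_hz)

  ratio <- NA_real_
  wp <- try(wave_power(p_beat, qs, fs_hz, config), silent = TRUE)
  if (!inherits(wp, "try-error")) {
    scale <- wp$n / length(p_beat)
    cls <- try(classify_waves(wp,
                              peak_idx = max(1L, round(which.max(p_beat) * scale)),
                              dn_idx = max(1L, round(lm$dn * scale)),
                              config = config),
               silent = TRUE)
    if (!inherits(cls, "try-error")) ratio <- cls$fcw_few_ratio
  }
  structure(list(pf = sep$pf, pb = sep$pb, pf_amp = sep$pf_amp,
                 pb_amp = sep$pb_amp, rm = sep$rm,
                 qzc_int = we$qzc_int, wasted_effort = we$wasted_effort,
                 wasted_ratio = we$wasted_ratio, fcw_few_ratio = ratio,
                 flow_source = "synthetic"),
            class = "pw_synth_result")
}
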