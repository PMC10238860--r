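#' Estimate aortic characteristic impedance from the early-systolic
#' pressure-flow slope
#'
#' Least-squares slope of diastole-zeroed pressure against flow over the
#' rising limb of ejection, from flow onset (last crossing of
#' `zc_low_frac * peak` before the peak) to flow reaching
#' `zc_high_frac * peak` (defaults 5% and 50%). During this window reflected
#' waves have not yet returned, so the loop slope approximates the
#' characteristic impedance. An alternative fixed-duration window
#' (`zc_mode = "fixed_ms"`) starts at flow onset and spans `zc_fixed_ms`.
#'
#' @param p pressure beat, mmHg (foot at the first sample).
#' @param q flow beat, mL/s.
#' @param fs_hz sampling rate.
#' @param config a [pw_config()].
#' @return A list: `zc` (mmHg·s/mL), `zc_min_l` (mmHg·min/L), `n` points in
#'   the window, `r2` of the fit, `window` (index range).
#' @export
estimate_zc <- function(p, q, fs_hz, config = pw_config()) {
  if (is.null(q)) stop("flow required for Zc estimation", call. = FALSE)
  if (length(p) != length(q)) stop("shape error: p and q lengths differ", call. = FALSE)
  ps <- p - min(p)
  ipk <- which.max(q)
  qmax <- q[ipk]
  if (!is.finite(qmax) || qmax <= 0)
    stop("fit error: no positive flow peak", call. = FALSE)
  below <- which(q[1:ipk] <= config$zc_low_frac * qmax)
  i0 <- if (length(below)) max(below) else 1L
  if (identical(config$zc_mode, "fixed_ms")) {
    i1 <- min(length(q), i0 + round(config$zc_fixed_ms / 1000 * fs_hz))
  } else {
    above <- which(q[i0:ipk] >= config$zc_high_frac * qmax)
    if (!length(above)) stop("window error: flow never reaches the upper fraction", call. = FALSE)
    i1 <- i0 + min(above) - 1L
  }
  idx <- i0:i1
  if (length(idx) < 4L)
    stop(sprintf("window error: only %d points in the Zc window (need >= 4)",
                 length(idx)), call. = FALSE)
  x <- q[idx]; y <- ps[idx]
  vx <- stats::var(x)
  if (vx <= 0) stop("fit error: zero flow variance in window", call. = FALSE)
  slope <- stats::cov(x, y) / vx
  if (slope <= 0)
    stop("fit error: non-positive pressure-flow slope (reflections in window or mis-segmentation)",
         call. = FALSE)
  r2 <- stats::cor(x, y)^2
  list(zc = slope, zc_min_l = slope * 1000 / 60, n = length(idx), r2 = r2,
       window = c(i0, i1))
}

#' Separate pressure into forward and backward waves
#'
#' With `ps = p - DBP` (diastolic pressure set to zero) and flow `q`:
#' `pf = (ps + q*zc)/2`, `pb = (ps - q*zc)/2` at every sample, so
#' `pf + pb = ps` and `pf - pb = q*zc` identically. Amplitudes are max minus
#' min of each series and the reflection magnitude is their ratio.
#'
#' @param p pressure beat, mmHg.
#' @param q flow beat (mL/s, or arbitrary units with a matching `zc`).
#' @param zc characteristic impedance consistent with the flow units.
#' @return A list of class `pw_wsa`: `pf`, `pb` (mmHg series), `pf_amp`,
#'   `pb_amp` (mmHg), `rm`, `zc`.
#' @export
separate_waves <- function(p, q, zc) {
  if (length(p) != length(q))
    stop("shape error: p and q lengths differ", call. = FALSE)
  if (!is.finite(zc) || zc <= 0) stop("zc must be positive", call. = FALSE)
  ps <- p - min(p)
  pf <- (ps + q * zc) / 2
  pb <- (ps - q * zc) / 2
  pf_amp <- max(pf) - min(pf)
  pb_amp <- max(pb) - min(pb)
  structure(list(pf = pf, pb = pb, pf_amp = pf_amp, pb_amp = pb_amp,
                 rm = reflection_magnitude(pb_amp, pf_amp), zc = zc),
            class = "pw_wsa")
}

#' Reflection magnitude
#'
#' Ratio of backward to forward pressure-wave amplitudes (Pb/Pf).
#'
#' @param pb_amp backward wave amplitude, mmHg.
#' @param pf_amp forward wave amplitude, mmHg (positive).
#' @return Dimensionless ratio.
#' @export
reflection_magnitude <- function(pb_amp, pf_amp) {
  if (!is.finite(pf_amp) || pf_amp <= 0)
    stop("pf_amp must be positive", call. = FALSE)
  pb_amp / pf_amp
}

#' Systolic QZc integral, wasted pressure effort and their ratio
#'
#' `qzc_int` is the trapezoidal integral of `q*zc` over systole (foot to
#' dicrotic notch) in mmHg·ms: the pulsatile pressure-time integral required
#' to drive the flow wave through the aortic root impedance. Wasted effort is
#' the integral of the excess of diastole-zeroed pressure over `q*zc`
#' (clamped at zero where flow-driven pressure exceeds measured pressure):
#' the reflection-attributable extra systolic load. Their ratio is a
#' dimensionless reflection index based on systolic pressure-time integrals
#' rather than amplitudes.
#'
#' @param p pressure beat, mmHg.
#' @param q flow beat.
#' @param zc characteristic impedance matching the flow units.
#' @param dn_idx dicrotic notch sample index within the beat.
#' @param fs_hz sampling rate.
#' @param foot_idx beat foot index (default 1).
#' @param dbp diastolic pressure override; defaults to `min(p)`.
#' @return A list: `qzc_int`, `wasted_effort` (mmHg·ms), `wasted_ratio`.
#' @export
wasted_effort_indices <- function(p, q, zc, dn_idx, fs_hz, foot_idx = 1L,
                                  dbp = NULL) {
  if (length(p) != length(q))
    stop("shape error: p and q lengths differ", call. = FALSE)
  if (is.na(dn_idx) || dn_idx <= foot_idx || dn_idx > length(p))
    stop("invalid dicrotic notch index", call. = FALSE)
  ps <- p - (dbp %||% min(p))
  idx <- foot_idx:dn_idx
  t_ms <- (idx - idx[1]) / fs_hz * 1000
  qzc <- q[idx] * zc
  qzc_int <- trapz(t_ms, qzc)
  if (qzc_int <= 0)
    stop("degenerate-beat error: non-positive QZc integral", call. = FALSE)
  wasted <- trapz(t_ms, pmax(ps[idx] - qzc, 0))
  list(qzc_int = qzc_int, wasted_effort = wasted,
       wasted_ratio = wasted / qzc_int)
}
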