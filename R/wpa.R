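#' Instantaneous wave power from paired pressure and flow
#'
#' Resamples pressure and flow to a canonical 500 Hz grid (per-sample
#' differences are rate-dependent, so a fixed grid keeps recordings
#' comparable), applies light Savitzky-Golay smoothing, and forms per-sample
#' first differences `dP` (mmHg) and `dQ` (mL/s). Wave power is
#' `dPi = dP * dQ * 133.322` in uW.
#'
#' @param p pressure beat, mmHg.
#' @param q flow beat, mL/s (or arbitrary units: only ratios of wave heights
#'   are then meaningful).
#' @param fs_hz sampling rate of the input.
#' @param config a [pw_config()].
#' @return A list of class `pw_power`: `dpi` (uW), `dP`, `dQ` (per-sample
#'   differences), `fs_hz` (the canonical rate), `n` (resampled length). The
#'   difference series are aligned so element `i` spans samples `i` to `i+1`.
#' @export
wave_power <- function(p, q, fs_hz, config = pw_config()) {
  if (length(p) != length(q))
    stop("shape error: p and q lengths differ", call. = FALSE)
  if (length(p) < 3L) stop("shape error: need at least 3 samples", call. = FALSE)
  fs_out <- config$wpa_hz
  n_out <- length(p)
  if (abs(fs_hz - fs_out) > 1e-9) {
    n_out <- max(3L, round(length(p) * fs_out / fs_hz))
    p <- resample_to(p, n_out)
    q <- resample_to(q, n_out)
  }
  w <- config$wpa_smooth
  if (n_out > w + 2L) {
    p <- signal::sgolayfilt(p, p = 3, n = w)
    q <- signal::sgolayfilt(q, p = 3, n = w)
  }
  dP <- diff(p)
  dQ <- diff(q)
  structure(list(dpi = convert_power_units(dP * dQ), dP = dP, dQ = dQ,
                 fs_hz = fs_out, n = n_out),
            class = "pw_power")
}

#' Classify forward compression, forward expansion and backward compression
#' waves
#'
#' Scans the wave-power series for the signature sign patterns:
#' FCW (+dPi, +dP, +dQ) as the largest positive power peak in early systole
#' (foot to peak pressure); FEW (+dPi, -dP, -dQ) as the largest positive
#' peak in late systole (peak pressure to the dicrotic notch plus a 20 ms
#' margin); BCW (-dPi, +dP, -dQ) as the largest-magnitude negative power in
#' systole. An absent BCW is a normal finding (no reflected energy), not an
#' error; an absent FCW flags the beat.
#'
#' @param wp a `pw_power` from [wave_power()].
#' @param peak_idx index of peak pressure on the resampled grid.
#' @param dn_idx index of the dicrotic notch on the resampled grid.
#' @param config a [pw_config()].
#' @return A list of class `pw_wpa`: `fcw`, `few`, `bcw` (each
#'   `(time_ms, height)` with heights in uW as positive magnitudes; `bcw` may
#'   be `NULL`), and `fcw_few_ratio`.
#' @export
classify_waves <- function(wp, peak_idx, dn_idx, config = pw_config()) {
  stopifnot(inherits(wp, "pw_power"))
  dpi <- wp$dpi; dP <- wp$dP; dQ <- wp$dQ
  nd <- length(dpi)
  margin <- round(config$few_margin_ms / 1000 * wp$fs_hz)
  peak_idx <- max(1L, min(peak_idx, nd))
  dn_hi <- max(1L, min(dn_idx + margin, nd))

  pick_max <- function(idx, cond, series) {
    cand <- idx[cond[idx]]
    if (!length(cand)) return(NULL)
    i <- cand[which.max(series[cand])]
    list(time_ms = (i - 0.5) / wp$fs_hz * 1000, height = abs(dpi[i]), idx = i)
  }
  early <- 1:peak_idx
  late <- peak_idx:dn_hi
  sys <- 1:min(dn_idx, nd)

  fcw <- pick_max(early, dpi > 0 & dP > 0 & dQ > 0, dpi)
  if (is.null(fcw))
    stop("classification error: no forward-compression-wave sample", call. = FALSE)
  few <- pick_max(late, dpi > 0 & dP < 0 & dQ < 0, dpi)
  bcw <- pick_max(sys, dpi < 0 & dP > 0 & dQ < 0, -dpi)

  ratio <- if (!is.null(few) && few$height > 0)
    fcw_few_ratio(fcw$height, few$height) else NA_real_
  structure(list(fcw = fcw, few = few, bcw = bcw, fcw_few_ratio = ratio),
            class = "pw_wpa")
}

#' Ratio of forward compression to forward expansion wave heights
#'
#' Dimensionless and invariant under any common rescaling of the flow units,
#' which is what makes it computable from uncalibrated synthetic flow.
#'
#' @param fcw_height FCW peak height.
#' @param few_height FEW peak height (positive).
#' @return `fcw_height / few_height`.
#' @export
fcw_few_ratio <- function(fcw_height, few_height) {
  if (!is.finite(few_height) || few_height <= 0)
    stop("few_height must be positive", call. = FALSE)
  fcw_height / few_height
}
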