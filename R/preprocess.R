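#' Filter an arterial pressure series
#'
#' Savitzky-Golay smoothing (window 23 samples, polynomial order 2) followed
#' by a zero-phase Butterworth low-pass at 10 Hz (applied forward and
#' backward, so symmetric pulses keep their peak position). The series is
#' reflection-padded before the recursive filter to suppress edge transients.
#'
#' @param p pressure series, mmHg.
#' @param fs_hz sampling rate (must exceed twice the cutoff).
#' @param config a [pw_config()].
#' @return Filtered series, same length as the input.
#' @export
filter_pressure <- function(p, fs_hz, config = pw_config()) {
  w <- config$savgol_window
  if (length(p) <= w)
    stop(sprintf("series too short for filtering: need > %d samples", w),
         call. = FALSE)
  if (fs_hz <= 2 * config$lowpass_hz)
    stop("sampling rate must exceed twice the low-pass cutoff", call. = FALSE)
  sm <- signal::sgolayfilt(p, p = config$savgol_order, n = w)
  bf <- signal::butter(2, config$lowpass_hz / (fs_hz / 2), type = "low")
  npad <- min(length(sm) - 1L, round(fs_hz))  # ~1 s reflection padding
  padded <- c(rev(sm[seq_len(npad) + 1L]), sm,
              rev(sm[length(sm) - seq_len(npad)]))
  out <- signal::filtfilt(bf, padded)
  out[(npad + 1L):(npad + length(sm))]
}

#' Detect beats in a filtered pressure series
#'
#' Locates systolic peaks as local maxima above the amplitude midline,
#' enforces a refractory interval (default one quarter of the median beat
#' period), and rejects candidate peaks whose amplitude deviates by more than
#' a configurable percentage from the 10-sample moving average of recent peak
#' amplitudes. Each beat's onset (foot) is the diastolic nadir preceding its
#' upstroke; a beat runs from its foot to the next foot (the final beat runs
#' to the end of the series).
#'
#' @param p filtered pressure, mmHg.
#' @param fs_hz sampling rate.
#' @param config a [pw_config()].
#' @return A data.frame of class `pw_beats` with columns `onset_idx`,
#'   `sys_peak_idx`, `end_idx` (1-based sample indices).
#' @export
detect_beats <- function(p, fs_hz, config = pw_config()) {
  n <- length(p)
  if (n < 3L) stop("detection error: series too short", call. = FALSE)
  rng <- range(p)
  if (diff(rng) < 1e-9)
    stop("detection error: no extrema in constant series", call. = FALSE)
  midline <- rng[1] + 0.4 * diff(rng)
  is_peak <- c(FALSE, p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n],
               FALSE)
  cand <- which(is_peak & p > midline)
  if (length(cand) < 2L)
    stop("detection error: fewer than 2 beats detected", call. = FALSE)

  ## refractory pruning: among peaks closer than refractory_frac of the beat
  ## period, keep the taller. Strongly augmented beats carry two systolic
  ## humps, so the period comes from the autocorrelation of the series (first
  ## dominant lag), not from candidate spacing.
  period <- estimate_period(p, fs_hz)
  refract <- config$refractory_frac * period
  keep <- cand[1]
  for (i in cand[-1]) {
    last <- keep[length(keep)]
    if (i - last < refract) {
      if (p[i] > p[last]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }

  ## plausibility: moving average (trailing window) of accepted peak heights
  thr <- config$plausibility_pct / 100
  acc <- integer(0)
  for (i in keep) {
    ref_heights <- utils::tail(p[acc], config$ma_window)
    if (length(ref_heights) >= 3L) {
      ma <- mean(ref_heights)
      span <- diff(rng)
      if (abs(p[i] - ma) > thr * max(ma - rng[1], 0.2 * span)) next
    }
    acc <- c(acc, i)
  }
  if (length(acc) < 2L)
    stop("detection error: fewer than 2 plausible beats", call. = FALSE)

  feet <- integer(length(acc))
  for (k in seq_along(acc)) {
    lo <- if (k == 1L) 1L else acc[k - 1L]
    seg <- p[lo:acc[k]]
    ## last occurrence of the minimum = nadir immediately preceding the upstroke
    nad <- lo + max(which(seg <= min(seg) + 1e-12)) - 1L
    feet[k] <- refine_foot(p, nad, acc[k])
  }
  segs <- data.frame(onset_idx = feet,
                     sys_peak_idx = acc,
                     end_idx = c(feet[-1], n))
  ok <- segs$onset_idx < segs$sys_peak_idx & segs$sys_peak_idx < segs$end_idx
  segs <- segs[ok, , drop = FALSE]
  if (nrow(segs) < 2L)
    stop("detection error: fewer than 2 well-formed beats", call. = FALSE)
  rownames(segs) <- NULL
  class(segs) <- c("pw_beats", "data.frame")
  segs
}

## beat period (in samples) from the first dominant autocorrelation peak in
## the physiologic band 0.2-2 s
estimate_period <- function(p, fs_hz) {
  lo <- max(2L, round(0.2 * fs_hz))
  hi <- min(length(p) - 2L, round(2 * fs_hz))
  if (hi <= lo) return(length(p) / 2)
  ac <- stats::acf(p, lag.max = hi, plot = FALSE, demean = TRUE)$acf[-1]
  lo + which.max(ac[lo:hi]) - 1L
}

## Low-pass filtering rounds the sharp diastolic-nadir corner and drags the
## smoothed minimum into the shallow decay limb. The corner itself survives as
## the curvature maximum, so the foot is refined from the smoothed nadir to
## the largest positive second difference between the nadir and the point
## where the upstroke reaches 20% of the local pulse height.
refine_foot <- function(p, nad, peak) {
  if (peak - nad < 6L) return(nad)
  rise20 <- p[nad] + 0.2 * (p[peak] - p[nad])
  hi <- nad + min(which(p[(nad + 1L):peak] >= rise20), peak - nad - 1L)
  win <- nad:hi
  if (length(win) < 5L) return(nad)
  curv <- diff(p[win], differences = 2)
  win[which.max(curv) + 1L]
}

#' Ensemble-average groups of beats on a normalized grid
#'
#' Consecutive groups of `group_size` beats (default 8) are each resampled to
#' a common length (`ensemble_n`, default 500), min-max amplitude normalized,
#' and averaged into one mean normalized waveform `fn` per group, with its
#' first through fifth finite-difference derivatives. Per-member time and
#' amplitude scales are retained so landmarks located on `fn` can be mapped
#' back to each contributing beat ([landmark_to_member()]). An incomplete
#' trailing group is discarded. If flow is supplied, a dimensional
#' (un-normalized) ensemble mean of pressure and flow is also stored for wave
#' separation / wave power on the averaged beat.
#'
#' @param beats a `pw_beats` data.frame from [detect_beats()].
#' @param p pressure series the beats index into.
#' @param q optional flow series (mL/s) on the same grid.
#' @param fs_hz sampling rate.
#' @param config a [pw_config()].
#' @return A list of `pw_ensemble` objects, each with `fn`, `d1`..`d5`,
#'   `members` (BeatSegment rows), `amp_scale` (per-member min/max),
#'   `mean_len` (mean member length, samples), `p_mean` and optional `q_mean`
#'   (dimensional ensemble means on the normalized grid), `fs_hz`.
#' @export
ensemble_average <- function(beats, p, q = NULL, fs_hz = NULL,
                             config = pw_config()) {
  g <- config$group_size
  nb <- nrow(beats)
  if (nb < g)
    stop(sprintf("grouping error: need at least %d beats, got %d", g, nb),
         call. = FALSE)
  n_out <- config$ensemble_n
  n_groups <- nb %/% g
  out <- vector("list", n_groups)
  for (grp in seq_len(n_groups)) {
    rows <- beats[((grp - 1L) * g + 1L):(grp * g), , drop = FALSE]
    mat <- matrix(NA_real_, n_out, g)
    pdim <- matrix(NA_real_, n_out, g)
    qdim <- if (!is.null(q)) matrix(NA_real_, n_out, g) else NULL
    amp <- matrix(NA_real_, g, 2, dimnames = list(NULL, c("min", "max")))
    lens <- integer(g)
    for (j in seq_len(g)) {
      idx <- rows$onset_idx[j]:rows$end_idx[j]
      lens[j] <- length(idx)
      y <- resample_to(p[idx], n_out)
      pdim[, j] <- y
      if (!is.null(qdim)) qdim[, j] <- resample_to(q[idx], n_out)
      amp[j, ] <- range(y)
      mat[, j] <- (y - amp[j, 1]) / (amp[j, 2] - amp[j, 1])
    }
    fn <- rowMeans(mat)
    ## renormalize the mean to exactly [0, 1]
    fn <- (fn - min(fn)) / (max(fn) - min(fn))
    d <- derivative_chain(fn, config = config)
    out[[grp]] <- structure(
      list(fn = fn, d1 = d$d1, d2 = d$d2, d3 = d$d3, d4 = d$d4, d5 = d$d5,
           members = rows, member_len = lens, amp_scale = amp,
           mean_len = mean(lens), p_mean = rowMeans(pdim),
           q_mean = if (!is.null(qdim)) rowMeans(qdim) else NULL,
           fs_hz = fs_hz, n_out = n_out),
      class = "pw_ensemble")
  }
  out
}

#' Map a normalized-grid landmark index back to a member beat
#'
#' Inverts the ensemble resampling: normalized index `k` on the `N`-point
#' grid maps to sample `onset_idx + round((k - 1) * (len - 1)/(N - 1))` of
#' member `j`.
#'
#' @param ens a `pw_ensemble`.
#' @param k normalized-grid index (1-based).
#' @param j member number within the group.
#' @return Absolute sample index in the original recording.
#' @export
landmark_to_member <- function(ens, k, j) {
  len <- ens$member_len[j]
  ens$members$onset_idx[j] + round((k - 1) * (len - 1) / (ens$n_out - 1))
}

#' First through fifth derivatives of a waveform by finite differences
#'
#' Successive central differences (one-sided at the endpoints) with light
#' Savitzky-Golay re-smoothing between orders (window 11, order 3 by default)
#' to control noise amplification at high orders.
#'
#' @param fn waveform (length at least 11).
#' @param dx grid spacing; defaults to `1/(length(fn)-1)` (a beat normalized
#'   to unit duration). Only the sign pattern matters for landmark logic.
#' @param config a [pw_config()].
#' @return A list `d1`..`d5`, each the same length as `fn`.
#' @export
derivative_chain <- function(fn, dx = NULL, config = pw_config()) {
  if (length(fn) < 11L)
    stop("length error: need at least 11 samples for the derivative chain",
         call. = FALSE)
  dx <- dx %||% (1 / (length(fn) - 1))
  w <- min(config$deriv_window,
           if (length(fn) %% 2 == 0) length(fn) - 1L else length(fn))
  out <- vector("list", 5)
  names(out) <- paste0("d", 1:5)
  g <- fn
  for (k in 1:5) {
    g <- num_gradient(g, dx)
    g <- signal::sgolayfilt(g, p = config$deriv_order, n = w)
    out[[k]] <- g
  }
  out
}
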