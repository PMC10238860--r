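#' Locate P1, P2 and the dicrotic notch on an ensemble waveform
#'
#' Implements the derivative-sign landmark algorithm on the mean normalized
#' waveform `fn`. The branch is chosen by the sign of the fifth derivative at
#' peak pressure:
#' \itemize{
#' \item Positive augmentation (`d5 < 0` at the peak): the maximum of `fn` is
#'   the late systolic peak P2; P1 is the second zero crossing of `d4` from
#'   positive to negative after the maximum of `d1` (steepest upstroke).
#' \item Negative augmentation (`d5 > 0`; an exact zero is treated as
#'   negative augmentation): the maximum of `fn` is P1; P2 is the first zero
#'   crossing of `d4` from negative to positive after P1.
#' }
#' In both branches the dicrotic notch is the first zero crossing of `d3`
#' from positive to negative after the pressure maximum that also follows
#' every systolic landmark (reflected waves still rising after the peak can
#' produce earlier, spurious curvature reversals).
#'
#' The ordinal position of the P1 crossing is not invariant across
#' reflection timings: when the reflected wave arrives close to the forward
#' peak the upstroke's own curvature reversal and the shoulder merge into a
#' single crossing. The locator therefore degrades gracefully: second
#' crossing, then first crossing (both must precede the peak), then the
#' negative-augmentation branch. A beat for which no consistent landmark set
#' exists is marked invalid with a reason and excluded from aggregation,
#' never silently filled. In the negative augmentation branch a missing P2
#' is tolerated (`p2_idx = NA`): the beat has no discernible reflected
#' shoulder, so augmented pressure and wasted effort are taken as
#' absent/zero downstream.
#'
#' @param ens a `pw_ensemble` from [ensemble_average()].
#' @return A list of class `pw_landmarks`: `p1_idx`, `p2_idx`, `dn_idx`
#'   (normalized-grid indices), `peak_idx`, `augmentation`
#'   (`"positive"`/`"negative"`), `valid`, `reason`.
#' @export
locate_landmarks <- function(ens) {
  stopifnot(inherits(ens, "pw_ensemble"))
  fn <- ens$fn
  n <- length(fn)
  imax <- which.max(fn)
  fail <- function(reason) {
    structure(list(p1_idx = NA_integer_, p2_idx = NA_integer_,
                   dn_idx = NA_integer_, peak_idx = imax,
                   augmentation = NA_character_, valid = FALSE,
                   reason = reason),
              class = "pw_landmarks")
  }
  if (imax <= 2L || imax >= n - 2L) return(fail("pressure peak at grid edge"))

  s5 <- ens$d5[imax]
  dn_cross <- zero_crossings(ens$d3, "down")
  ## physiologic ejection window: at 60-130 bpm the notch falls between
  ## ~27% and ~55% of the cycle; earlier d3 reversals are reflected-wave
  ## curvature, later ones diastolic decay structure
  dn_cross <- dn_cross[dn_cross > imax &
                       dn_cross >= ceiling(0.27 * n) &
                       dn_cross <= floor(0.55 * n)]
  if (!length(dn_cross)) return(fail("no dicrotic-notch crossing in d3"))
  ## the notch must follow every systolic landmark; spurious mid-systolic
  ## curvature reversals (reflected wave still rising) are skipped
  pick_dn <- function(after) {
    ok <- dn_cross[dn_cross > after]
    if (length(ok)) ok[1L] else NA_integer_
  }

  p1 <- p2 <- NA_integer_
  augmentation <- NA_character_
  if (s5 < 0) {
    ## positive augmentation: fn max is P2; P1 is the d4 down-crossing after
    ## the steepest upstroke — the second when the upstroke carries its own
    ## early curvature reversal, otherwise the first (the two inflection
    ## features merge when the reflection arrives close to the forward peak)
    i_up <- which.max(ens$d1)
    cross <- zero_crossings(ens$d4, "down")
    cross <- cross[cross > i_up]
    cand <- c(if (length(cross) >= 2L) cross[2L], if (length(cross)) cross[1L])
    cand <- cand[!is.na(cand) & cand < imax]
    if (length(cand)) {
      augmentation <- "positive"
      p1 <- cand[1L]
      p2 <- imax
    }
  }
  if (is.na(p1)) {
    ## negative augmentation (d5 >= 0 at the peak, exact zero included, or no
    ## consistent positive-branch landmark set): fn max is P1; P2 is the
    ## first d4 up-crossing after it
    augmentation <- "negative"
    p1 <- imax
    cross <- zero_crossings(ens$d4, "up")
    cross <- cross[cross > p1]
    p2 <- if (length(cross)) cross[1L] else NA_integer_
    dn <- pick_dn(max(p1, p2, na.rm = TRUE))
    if (is.na(dn) && !is.na(p2)) {  # drop an implausibly late P2
      p2 <- NA_integer_
      dn <- pick_dn(p1)
    }
  } else {
    dn <- pick_dn(max(p1, p2, na.rm = TRUE))
  }
  if (is.na(dn)) return(fail("dicrotic notch not after systolic landmarks"))
  structure(list(p1_idx = as.integer(p1), p2_idx = as.integer(p2),
                 dn_idx = as.integer(dn), peak_idx = as.integer(imax),
                 augmentation = augmentation, valid = TRUE, reason = NA_character_),
            class = "pw_landmarks")
}

#' Pulse wave analysis indices for one member beat
#'
#' Computes the dimensional pressure-time indices of a single beat from its
#' pressure segment (mmHg) and its landmarks (local indices within the
#' segment). Areas use trapezoidal integration with time in milliseconds.
#'
#' @param p_seg pressure segment from foot to next foot, mmHg.
#' @param lm list with local 1-based indices `p1`, `p2` (may be `NA`), `dn`,
#'   and `augmentation` (`"positive"` or `"negative"`).
#' @param fs_hz sampling rate.
#' @return One-row data.frame: `sbp`, `dbp`, `map` (mmHg), `hr` (bpm), `ap`
#'   (mmHg, late minus early systolic peak), `ed_ms`, `tr_ms`, `sdr_ms`,
#'   `ew`, `psa`, `spti`, `delta_spti`, `dpti` (mmHg·ms). The identities
#'   `ed = tr + sdr` and `spti = delta_spti + psa + ew` hold by construction.
#' @export
compute_pwa_indices <- function(p_seg, lm, fs_hz) {
  n <- length(p_seg)
  dn <- lm$dn
  p1 <- lm$p1
  p2 <- lm$p2
  if (is.na(dn) || is.na(p1) || dn < 2L || dn > n || p1 < 1L || p1 > dn)
    stop("landmarks invalid for index computation", call. = FALSE)
  t_ms <- (seq_len(n) - 1) / fs_hz * 1000
  dbp <- p_seg[1]
  sbp <- max(p_seg)
  map <- mean(p_seg)
  hr <- 60000 / t_ms[n]

  ap <- if (is.na(p2)) NA_real_ else p_seg[p2] - p_seg[p1]
  ed_ms <- t_ms[dn]
  tr_ms <- t_ms[p1]
  sdr_ms <- ed_ms - tr_ms

  infl <- if (identical(lm$augmentation, "negative")) p2 else p1
  ew <- 0
  if (!is.na(infl) && infl < dn) {
    seg <- infl:dn
    ew <- trapz(t_ms[seg], pmax(p_seg[seg] - p_seg[infl], 0))
  }
  sys <- 1:dn
  area_above_dbp <- trapz(t_ms[sys], p_seg[sys] - dbp)
  psa <- area_above_dbp - ew
  spti <- trapz(t_ms[sys], p_seg[sys])
  delta_spti <- spti - psa - ew
  dpti <- if (dn < n) trapz(t_ms[dn:n], p_seg[dn:n]) else 0

  for (nm in c("ew", "psa", "spti", "delta_spti", "dpti")) {
    v <- get(nm)
    if (v < -1e-9 * max(spti, 1))
      stop(sprintf("internal-consistency error: negative area '%s'", nm),
           call. = FALSE)
    assign(nm, max(v, 0))
  }
  data.frame(sbp = sbp, dbp = dbp, map = map, hr = hr, ap = ap,
             ed_ms = ed_ms, tr_ms = tr_ms, sdr_ms = sdr_ms,
             ew = ew, psa = psa, spti = spti, delta_spti = delta_spti,
             dpti = dpti)
}

#' Aggregate per-beat indices into a session summary
#'
#' Arithmetic mean and standard deviation per index over all valid beats,
#' plus the count of excluded beats.
#'
#' @param per_beat data.frame of per-beat index rows (only valid beats).
#' @param n_excluded number of beats excluded by landmark failures.
#' @return A list with `mean` and `sd` (named numeric vectors over the
#'   numeric columns), `n_beats`, `n_excluded`.
#' @export
aggregate_session <- function(per_beat, n_excluded = 0L) {
  if (is.null(per_beat) || nrow(per_beat) < 1L)
    stop("aggregation error: no valid beats", call. = FALSE)
  num <- per_beat[vapply(per_beat, is.numeric, logical(1))]
  list(mean = vapply(num, function(x) mean(x, na.rm = TRUE), numeric(1)),
       sd = vapply(num, function(x) stats::sd(x[!is.na(x)]), numeric(1)),
       n_beats = nrow(per_beat),
       n_excluded = as.integer(n_excluded))
}
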