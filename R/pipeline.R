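#' End-to-end analysis of a pressure(-flow) recording
#'
#' Runs the full chain: pressure filtering, beat detection, 8-beat ensemble
#' averaging, landmark location on each ensemble waveform, per-beat pulse
#' wave analysis, per-beat wave separation (measured flow, when present, and
#' synthetic flow), per-group wave power analysis on the dimensional
#' ensemble mean, and measured-vs-synthetic agreement statistics. The result
#' is deterministic for a fixed recording and configuration; every excluded
#' beat is counted.
#'
#' @param rec a [recording()].
#' @param config a [pw_config()].
#' @return A list of class `pw_session`:
#' \itemize{
#' \item `groups`: data.frame, one row per (ensemble group, flow source),
#'   with PWA group means and WSA/WPA indices (`flow_source` label;
#'   absolute `zc`/`fcw_height`/`few_height` only for measured flow).
#' \item `per_beat`: per-member-beat indices for both flow sources.
#' \item `summary`: session mean/SD per flow source.
#' \item `agreement`: per-index Bland-Altman bias and 95% limits of
#'   agreement plus Spearman's rho between measured- and synthetic-flow
#'   per-beat values (present only when both sources were computed).
#' \item `excluded`: count and reasons of excluded beats/groups.
#' }
#' @export
analyze_recording <- function(rec, config = pw_config()) {
  stopifnot(inherits(rec, "pw_recording"))
  pf <- filter_pressure(rec$p, rec$fs_hz, config)
  ## WSA/WPA and flow synthesis run on lightly smoothed pressure: the 10 Hz
  ## low-pass needed for landmark derivatives flattens the early-systolic
  ## upstroke and would bias the pressure-flow slope (Zc) low
  p_wsa <- signal::sgolayfilt(rec$p, p = config$savgol_order,
                              n = config$savgol_window)
  ## flow gets the same linear smoother: unequal filtering of p and q would
  ## bias the pressure-flow slope even on noise-free data
  q_wsa <- if (!is.null(rec$q))
    signal::sgolayfilt(rec$q, p = config$savgol_order,
                       n = config$savgol_window) else NULL
  beats <- detect_beats(pf, rec$fs_hz, config)
  if (nrow(beats) < config$group_size)
    stop(sprintf("session error: need at least %d beats for one ensemble group, got %d",
                 config$group_size, nrow(beats)), call. = FALSE)
  groups <- ensemble_average(beats, pf, q = rec$q, fs_hz = rec$fs_hz,
                             config = config)
  has_flow <- !is.null(rec$q)
  fs <- rec$fs_hz

  per_beat <- list()
  group_rows <- list()
  excluded <- character(0)

  for (gi in seq_along(groups)) {
    ens <- groups[[gi]]
    lmk <- locate_landmarks(ens)
    if (!isTRUE(lmk$valid)) {
      excluded <- c(excluded, sprintf("group %d: %s", gi, lmk$reason))
      next
    }
    g <- nrow(ens$members)
    pwa_rows <- meas_rows <- syn_rows <- list()
    for (j in seq_len(g)) {
      seg_idx <- ens$members$onset_idx[j]:ens$members$end_idx[j]
      p_seg <- pf[seg_idx]
      to_local <- function(k) {
        if (is.na(k)) return(NA_integer_)
        min(length(seg_idx),
            max(1L, landmark_to_member(ens, k, j) - ens$members$onset_idx[j] + 1L))
      }
      lm_j <- list(p1 = to_local(lmk$p1_idx), p2 = to_local(lmk$p2_idx),
                   dn = to_local(lmk$dn_idx), peak = to_local(lmk$peak_idx),
                   augmentation = lmk$augmentation)
      row <- try(compute_pwa_indices(p_seg, lm_j, fs), silent = TRUE)
      if (inherits(row, "try-error")) {
        excluded <- c(excluded, sprintf("group %d beat %d: PWA failed", gi, j))
        next
      }
      row$group <- gi; row$beat <- j
      pwa_rows[[length(pwa_rows) + 1L]] <- row

      pw_seg <- p_wsa[seg_idx]
      if (has_flow) {
        q_seg <- q_wsa[seg_idx]
        m <- try({
          fit <- estimate_zc(pw_seg, q_seg, fs, config)
          sep <- separate_waves(pw_seg, q_seg, fit$zc)
          we <- wasted_effort_indices(pw_seg, q_seg, fit$zc, lm_j$dn, fs)
          sv <- trapz((seg_idx - seg_idx[1]) / fs, pmax(rec$q[seg_idx], 0))
          data.frame(group = gi, beat = j, sv_ml = sv, zc = fit$zc,
                     zc_min_l = fit$zc_min_l, zc_r2 = fit$r2,
                     pf_amp = sep$pf_amp, pb_amp = sep$pb_amp, rm = sep$rm,
                     qzc_int = we$qzc_int, wasted_effort = we$wasted_effort,
                     wasted_ratio = we$wasted_ratio)
        }, silent = TRUE)
        if (!inherits(m, "try-error"))
          meas_rows[[length(meas_rows) + 1L]] <- m
        else excluded <- c(excluded, sprintf("group %d beat %d: measured-flow WSA failed", gi, j))
      }
      s <- try({
        ## synthesis needs the notch morphology the 10 Hz low-pass removes
        sf <- synthesize_flow(pw_seg, lm_j, fs)
        res <- wsa_wpa_from_synthetic(pw_seg, sf, lm_j, fs, config)
        data.frame(group = gi, beat = j, pf_amp = res$pf_amp,
                   pb_amp = res$pb_amp, rm = res$rm, qzc_int = res$qzc_int,
                   wasted_effort = res$wasted_effort,
                   wasted_ratio = res$wasted_ratio,
                   fcw_few_ratio = res$fcw_few_ratio)
      }, silent = TRUE)
      if (!inherits(s, "try-error"))
        syn_rows[[length(syn_rows) + 1L]] <- s
      else excluded <- c(excluded, sprintf("group %d beat %d: synthetic flow failed", gi, j))
    }
    if (!length(pwa_rows)) next
    pwa_df <- do.call(rbind, pwa_rows)
    meas_df <- if (length(meas_rows)) do.call(rbind, meas_rows) else NULL
    syn_df <- if (length(syn_rows)) do.call(rbind, syn_rows) else NULL

    ## group-level WPA on the dimensional ensemble mean
    wpa_meas <- wpa_group(ens, lmk, config, source = "measured")
    wpa_syn <- NULL

    base <- c(list(group = gi, n_members = g, augmentation = lmk$augmentation),
              as.list(colMeans(pwa_df[setdiff(names(pwa_df), c("group", "beat"))],
                               na.rm = TRUE)))
    if (has_flow && !is.null(meas_df)) {
      r <- c(base, list(flow_source = "measured"),
             as.list(colMeans(meas_df[setdiff(names(meas_df), c("group", "beat"))])),
             list(fcw_height = wpa_meas$fcw_height %||% NA_real_,
                  few_height = wpa_meas$few_height %||% NA_real_,
                  bcw_height = wpa_meas$bcw_height %||% NA_real_,
                  fcw_few_ratio = wpa_meas$fcw_few_ratio %||% NA_real_))
      group_rows[[length(group_rows) + 1L]] <- as.data.frame(r)
    }
    if (!is.null(syn_df)) {
      r <- c(base, list(flow_source = "synthetic"),
             as.list(colMeans(syn_df[setdiff(names(syn_df), c("group", "beat"))],
                              na.rm = TRUE)))
      group_rows[[length(group_rows) + 1L]] <- as.data.frame(r)
    }
    pwa_df$flow_source <- "pressure"
    if (!is.null(meas_df)) meas_df$flow_source <- "measured"
    if (!is.null(syn_df)) syn_df$flow_source <- "synthetic"
    per_beat[[length(per_beat) + 1L]] <-
      list(pwa = pwa_df, measured = meas_df, synthetic = syn_df)
  }
  if (!length(group_rows))
    stop("session error: no ensemble group produced valid results", call. = FALSE)

  groups_df <- do.call(rbind_fill, group_rows)
  pwa_all <- do.call(rbind, lapply(per_beat, `[[`, "pwa"))
  meas_all <- do.call(rbind, Filter(Negate(is.null),
                                    lapply(per_beat, `[[`, "measured")))
  syn_all <- do.call(rbind, Filter(Negate(is.null),
                                   lapply(per_beat, `[[`, "synthetic")))

  summary <- lapply(split(groups_df, groups_df$flow_source), function(d) {
    num <- d[vapply(d, is.numeric, logical(1))]
    num <- num[setdiff(names(num), c("group", "n_members"))]
    list(mean = colMeans(num, na.rm = TRUE),
         sd = vapply(num, function(x) stats::sd(x[!is.na(x)]), numeric(1)))
  })

  agreement <- NULL
  if (!is.null(meas_all) && !is.null(syn_all)) {
    key <- c("group", "beat")
    merged <- merge(meas_all, syn_all, by = key, suffixes = c("_meas", "_syn"))
    idxs <- c("pf_amp", "pb_amp", "rm", "qzc_int", "wasted_effort", "wasted_ratio")
    agreement <- do.call(rbind, lapply(idxs, function(nm) {
      x <- merged[[paste0(nm, "_meas")]]
      y <- merged[[paste0(nm, "_syn")]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3L) return(NULL)
      ba <- bland_altman(x[ok], y[ok])
      data.frame(index = nm, n = sum(ok), bias = ba$bias,
                 loa_low = ba$loa_low, loa_high = ba$loa_high,
                 rho = spearman_rho(x[ok], y[ok]))
    }))
  }
  structure(list(groups = groups_df,
                 per_beat = list(pwa = pwa_all, measured = meas_all,
                                 synthetic = syn_all),
                 summary = summary, agreement = agreement,
                 excluded = list(n = length(excluded), reasons = excluded),
                 meta = list(fs_hz = fs, n_beats = nrow(beats),
                             n_groups = length(groups),
                             has_flow = has_flow, config = unclass(config))),
            class = "pw_session")
}

## WPA on the dimensional ensemble mean of one group
wpa_group <- function(ens, lmk, config, source = "measured") {
  if (is.null(ens$q_mean) || is.null(ens$fs_hz)) return(list())
  ## the normalized grid spans the mean beat duration
  fs_eff <- ens$n_out / (ens$mean_len / ens$fs_hz)
  wp <- try(wave_power(ens$p_mean, ens$q_mean, fs_eff, config), silent = TRUE)
  if (inherits(wp, "try-error")) return(list())
  scale <- wp$n / ens$n_out
  cls <- try(classify_waves(wp,
                            peak_idx = max(1L, round(lmk$peak_idx * scale)),
                            dn_idx = max(1L, round(lmk$dn_idx * scale)),
                            config = config),
             silent = TRUE)
  if (inherits(cls, "try-error")) return(list())
  list(fcw_height = cls$fcw$height, few_height = cls$few$height %||% NA_real_,
       bcw_height = if (is.null(cls$bcw)) NA_real_ else cls$bcw$height,
       fcw_few_ratio = cls$fcw_few_ratio)
}

## rbind data.frames with unequal column sets (missing columns filled with NA)
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    miss <- setdiff(cols, names(d))
    for (m in miss) d[[m]] <- NA
    d[cols]
  }))
}

#' @export
print.pw_session <- function(x, ...) {
  cat(sprintf("<pw_session> %d beats, %d ensemble group(s), flow %s\n",
              x$meta$n_beats, x$meta$n_groups,
              if (x$meta$has_flow) "measured+synthetic" else "synthetic only"))
  cat(sprintf("  excluded: %d\n", x$excluded$n))
  invisible(x)
}

#' Bland-Altman agreement statistics
#'
#' Mean bias of the paired differences `x - y` and 95% limits of agreement
#' `bias +/- 1.96 * SD` (sample SD, n-1 denominator).
#'
#' @param x,y equal-length paired measurements.
#' @return A list: `bias`, `loa_low`, `loa_high`, `sd`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y))
    stop("paired samples must have equal length", call. = FALSE)
  if (length(x) < 2L)
    stop("insufficient data: need at least 2 pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd = s, n = length(d))
}

#' Spearman's rank correlation
#'
#' Pearson correlation of average-ranked values (ties get average ranks).
#' Returns `NA` with a warning when either ranking has zero variance.
#'
#' @param x,y equal-length samples, n >= 3.
#' @return Spearman's rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop("samples must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    warning("zero rank variance: Spearman's rho undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Write a session report to a delimited file
#'
#' Writes one wide comma-delimited table for the chosen flow source: one row
#' per ensemble group followed by a session-mean summary row. Column names
#' carry units.
#'
#' @param results a `pw_session` from [analyze_recording()].
#' @param path output path.
#' @param flow_source which block to write (`"measured"` or `"synthetic"`).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, flow_source = NULL) {
  if (!inherits(results, "pw_session") || is.null(results$groups) ||
      !nrow(results$groups))
    stop("empty results: nothing to write", call. = FALSE)
  src <- flow_source %||%
    (if (results$meta$has_flow) "measured" else "synthetic")
  d <- results$groups[results$groups$flow_source == src, , drop = FALSE]
  if (!nrow(d))
    stop(sprintf("empty results: no rows for flow source '%s'", src),
         call. = FALSE)
  num <- vapply(d, is.numeric, logical(1))
  smry <- d[1, , drop = FALSE]
  smry[num] <- as.list(colMeans(d[num], na.rm = TRUE))
  smry$group <- NA
  smry$row_type <- "session_mean"
  d$row_type <- "ensemble_group"
  out <- rbind(d, smry)
  units <- c(sbp = "mmHg", dbp = "mmHg", map = "mmHg", hr = "bpm",
             ap = "mmHg", ed_ms = "ms", tr_ms = "ms", sdr_ms = "ms",
             ew = "mmHg.ms", psa = "mmHg.ms", spti = "mmHg.ms",
             delta_spti = "mmHg.ms", dpti = "mmHg.ms",
             zc = "mmHg.s.mL", zc_min_l = "mmHg.min.L",
             pf_amp = "mmHg", pb_amp = "mmHg",
             qzc_int = "mmHg.ms", wasted_effort = "mmHg.ms",
             fcw_height = "uW", few_height = "uW", bcw_height = "uW")
  nm <- names(out)
  lab <- ifelse(nm %in% names(units), paste0(nm, "_", units[nm]), nm)
  ## ed/tr/sdr already carry _ms
  lab <- sub("_ms_ms$", "_ms", lab)
  names(out) <- lab
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
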