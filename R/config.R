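#' Analysis configuration defaults
#'
#' Returns the tunable parameters of the analysis chain with their defaults.
#' Any subset can be overridden by name.
#'
#' @param ... named overrides.
#' @return A named list of class `pw_config`.
#' @details
#' * `savgol_window` (23 samples), `savgol_order` (2): Savitzky-Golay
#'   pressure smoothing.
#' * `lowpass_hz` (10): zero-phase Butterworth low-pass cutoff.
#' * `ensemble_n` (500): length of the normalized ensemble grid.
#' * `group_size` (8): beats per ensemble group.
#' * `refractory_frac` (0.25): minimum peak spacing as a fraction of the
#'   median beat period.
#' * `plausibility_pct` (30): rejection threshold (percent) around the
#'   10-peak moving average of systolic peak amplitudes.
#' * `deriv_window` (11), `deriv_order` (3): Savitzky-Golay re-smoothing
#'   between derivative orders.
#' * `zc_low_frac` (0.05), `zc_high_frac` (0.50), `zc_mode`
#'   (`"fraction"` or `"fixed_ms"`), `zc_fixed_ms` (60): early-systolic
#'   pressure-flow slope window for Zc.
#' * `wpa_hz` (500): canonical resampling rate before differencing;
#'   `wpa_smooth` (9): light smoothing window; `few_margin_ms` (20): FEW
#'   search margin beyond the dicrotic notch.
#' @export
pw_config <- function(...) {
  cfg <- list(
    savgol_window = 23, savgol_order = 2, lowpass_hz = 10,
    ensemble_n = 500, group_size = 8,
    refractory_frac = 0.25, plausibility_pct = 30, ma_window = 10,
    deriv_window = 11, deriv_order = 3,
    zc_low_frac = 0.05, zc_high_frac = 0.50,
    zc_mode = "fraction", zc_fixed_ms = 60,
    wpa_hz = 500, wpa_smooth = 9, few_margin_ms = 20
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  cfg[names(dots)] <- dots
  class(cfg) <- "pw_config"
  cfg
}
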