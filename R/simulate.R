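#' Simulation parameters for the tube-load pressure-flow generator
#'
#' Bundles the generative parameters of the paired pressure-flow simulator:
#' a forward ejection wave of characteristic-impedance-scaled pressure plus a
#' delayed, attenuated reflection. Every parameter is ground truth that the
#' analysis chain (Zc estimation, wave separation, wave power) can be tested
#' against.
#'
#' @param zc_true characteristic impedance, mmHg·s/mL.
#' @param gamma reflection coefficient in `[0, 1)`; equals the generative
#'   reflection magnitude (backward/forward amplitude ratio).
#' @param tau_ms round-trip reflection delay, ms; must be below `ed_ms` so the
#'   reflected wave arrives in systole.
#' @param hr_bpm heart rate, beats/min.
#' @param ed_ms ejection duration, ms; must be below the beat period.
#' @param sv_ml stroke volume, mL (integral of positive aortic flow per beat).
#' @param dbp_mmhg diastolic (foot) pressure, mmHg.
#' @param tau_decay_ms exponential diastolic decay constant, ms.
#' @param noise_sd_mmhg SD of additive white Gaussian pressure noise, mmHg.
#' @param noise_sd_flow SD of additive white Gaussian flow noise, mL/s.
#' @param fs_hz sampling rate, Hz.
#' @param seed integer RNG seed; `NULL` leaves the RNG state alone.
#' @param frac_tp time of peak forward flow as a fraction of `ed_ms`; smaller
#'   values give the rapid upstroke / slow decline of a vigorously
#'   contracting ventricle.
#' @param shape_a exponent of the smooth ejection lobe
#'   `(u e^(1-u))^shape_a` with `u = t/tp`: larger values give a more
#'   symmetric, sigmoid-onset lobe (slower pressure rise, the signature of
#'   reduced contractility); smaller values a sharper upstroke.
#' @param inc_width_ms width of the incisura (dicrotic-notch) flow lobe, ms.
#' @param inc_frac incisura lobe depth as a fraction of peak forward flow.
#'
#' @return An object of class `pw_sim_params` (a validated list).
#' @seealso [simulate_beat()], [simulate_recording()], [hf_preset()]
#' @export
sim_params <- function(zc_true = 0.1134, gamma = 0.48, tau_ms = 100,
                       hr_bpm = 86.5, ed_ms = 230, sv_ml = 41.2,
                       dbp_mmhg = 68, tau_decay_ms = 350,
                       noise_sd_mmhg = 0, noise_sd_flow = 0,
                       fs_hz = 500, seed = NULL,
                       frac_tp = 0.33, shape_a = 2,
                       inc_width_ms = 30, inc_frac = 0.15) {
  p <- list(zc_true = zc_true, gamma = gamma, tau_ms = tau_ms,
            hr_bpm = hr_bpm, ed_ms = ed_ms, sv_ml = sv_ml,
            dbp_mmhg = dbp_mmhg, tau_decay_ms = tau_decay_ms,
            noise_sd_mmhg = noise_sd_mmhg, noise_sd_flow = noise_sd_flow,
            fs_hz = fs_hz, seed = seed,
            frac_tp = frac_tp, shape_a = shape_a,
            inc_width_ms = inc_width_ms, inc_frac = inc_frac)
  validate_sim_params(p)
  class(p) <- "pw_sim_params"
  p
}

validate_sim_params <- function(p) {
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_field(field, "must be a finite numeric scalar")
    v
  }
  for (f in c("zc_true", "hr_bpm", "ed_ms", "sv_ml", "dbp_mmhg",
              "tau_decay_ms", "fs_hz"))
    if (num1(f) <= 0) stop_field(f, "must be strictly positive")
  if (num1("gamma") < 0 || p$gamma >= 1)
    stop_field("gamma", "must lie in [0, 1)")
  if (num1("tau_ms") < 0) stop_field("tau_ms", "must be non-negative")
  period_ms <- 60000 / p$hr_bpm
  if (p$ed_ms >= period_ms)
    stop_field("ed_ms", sprintf("must be below the beat period (%.1f ms)", period_ms))
  if (p$tau_ms >= p$ed_ms)
    stop_field("tau_ms", "must be below ed_ms (reflection arrives in systole)")
  if (num1("noise_sd_mmhg") < 0) stop_field("noise_sd_mmhg", "must be non-negative")
  if (num1("noise_sd_flow") < 0) stop_field("noise_sd_flow", "must be non-negative")
  if (num1("frac_tp") <= 0 || p$frac_tp >= 1)
    stop_field("frac_tp", "must lie in (0, 1)")
  if (num1("shape_a") <= 0) stop_field("shape_a", "must be positive")
  if (num1("inc_width_ms") <= 0) stop_field("inc_width_ms", "must be positive")
  if (num1("inc_frac") < 0) stop_field("inc_frac", "must be non-negative")
  invisible(p)
}

## unit-amplitude forward-wave pressure shape on time grid t (seconds):
## smooth asymmetric ejection lobe s(u) = (u e^(1-u))^a with u = t/tp (C-inf,
## peak 1 at tp, sigmoid onset), truncated at end-ejection where the
## exponential diastolic decay takes over; an incisura lobe spans
## [ed, ed + w]
forward_shape <- function(t, ed, tp, a, taud, w, inc_frac) {
  s <- numeric(length(t))
  i_sys <- t >= 0 & t <= ed
  u <- t[i_sys] / tp
  s[i_sys] <- (u * exp(1 - u))^a
  end_lv <- ((ed / tp) * exp(1 - ed / tp))^a
  i_inc <- t > ed & t <= ed + w
  v <- t[i_inc] - ed
  s[i_inc] <- end_lv * exp(-v / taud) - inc_frac * sin(pi * v / w)
  i_dia <- t > ed + w
  s[i_dia] <- end_lv * exp(-(t[i_dia] - ed) / taud)
  s
}

#' Simulate one paired aortic pressure-flow beat with exact ground truth
#'
#' Generates a single beat of the tube-load model: a forward pressure wave
#' `pf = Zc * q0` (asymmetric ejection lobe with incisura and exponential
#' diastolic decay), a backward wave `pb(t) = gamma * pf(t - tau)`, pressure
#' `p = DBP + pf + pb + noise` and flow `q = (pf - pb)/Zc + noise`. The flow
#' amplitude is scaled so the positive-flow integral equals the requested
#' stroke volume. Before noise injection the conservation identities
#' `p - DBP = pf + pb` and `q = (pf - pb)/Zc` hold at machine precision.
#'
#' @param params a [sim_params()] object.
#' @return A list of class `pw_beat` with fields `t` (s), `p` (mmHg),
#'   `q` (mL/s), `pf_true`, `pb_true` (mmHg, diastole-zeroed), and `truth`
#'   (the parameters plus derived quantities: peak forward flow `a_peak`,
#'   incisura window sample indices `inc_window`).
#' @export
simulate_beat <- function(params) {
  validate_sim_params(params)
  if (!is.null(params$seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(params$seed)
  }
  simulate_beat_core(params, period_s = 60 / params$hr_bpm)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

simulate_beat_core <- function(params, period_s) {
  fs <- params$fs_hz
  n <- max(3L, round(period_s * fs))
  t <- (seq_len(n) - 1) / fs
  ed <- params$ed_ms / 1000
  tp <- params$frac_tp * ed
  w <- params$inc_width_ms / 1000
  taud <- params$tau_decay_ms / 1000
  tau <- params$tau_ms / 1000

  s_f <- forward_shape(t, ed, tp, params$shape_a, taud, w, params$inc_frac)
  s_b <- params$gamma * forward_shape(t - tau, ed, tp, params$shape_a,
                                      taud, w, params$inc_frac)
  s_b[t < tau] <- 0

  ## scale so that the positive-flow integral equals sv_ml (flow is linear in
  ## the amplitude, so one pass suffices)
  q_unit <- s_f - s_b
  pos_int <- trapz(t, pmax(q_unit, 0))
  if (pos_int <= 0) stop("degenerate beat: no positive flow", call. = FALSE)
  a_peak <- params$sv_ml / pos_int

  pf <- params$zc_true * a_peak * s_f
  pb <- params$zc_true * a_peak * s_b
  q <- a_peak * q_unit
  p <- params$dbp_mmhg + pf + pb
  if (params$noise_sd_mmhg > 0) p <- p + stats::rnorm(n, 0, params$noise_sd_mmhg)
  if (params$noise_sd_flow > 0) q <- q + stats::rnorm(n, 0, params$noise_sd_flow)

  truth <- params
  truth$a_peak <- a_peak
  truth$inc_window <- c(floor(ed * fs) + 1L, ceiling((ed + w) * fs) + 1L)
  structure(list(t = t, p = p, q = q, pf_true = pf, pb_true = pb,
                 truth = truth),
            class = "pw_beat")
}

#' Simulate a multi-beat recording with per-beat period jitter
#'
#' Concatenates [simulate_beat()] output with multiplicative Gaussian jitter
#' on the beat period. Output is bitwise reproducible for a fixed
#' `params$seed`.
#'
#' @param params a [sim_params()] object (its `seed` drives all randomness).
#' @param n_beats number of beats, at least 1.
#' @param jitter_frac SD of the per-beat period factor (default 2%).
#' @return A [recording()] whose `truth` attribute holds the parameters and
#'   the 1-based start sample of every beat.
#' @export
simulate_recording <- function(params, n_beats, jitter_frac = 0.02) {
  validate_sim_params(params)
  if (!is.numeric(n_beats) || length(n_beats) != 1L || n_beats < 1)
    stop("n_beats must be a positive integer", call. = FALSE)
  n_beats <- as.integer(n_beats)
  if (!is.null(params$seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(params$seed)
  }
  base_period <- 60 / params$hr_bpm
  factors <- if (jitter_frac > 0) {
    pmax(1 + stats::rnorm(n_beats, 0, jitter_frac), params$ed_ms / 1000 / base_period + 0.05)
  } else rep(1, n_beats)

  p <- q <- pf <- pb <- numeric(0)
  starts <- integer(n_beats)
  for (k in seq_len(n_beats)) {
    starts[k] <- length(p) + 1L
    b <- simulate_beat_core(params, period_s = base_period * factors[k])
    p <- c(p, b$p); q <- c(q, b$q)
    pf <- c(pf, b$pf_true); pb <- c(pb, b$pb_true)
  }
  t <- (seq_along(p) - 1) / params$fs_hz
  rec <- recording(t = t, p = p, q = q, fs_hz = params$fs_hz,
                   meta = list(source = "simulated"))
  attr(rec, "truth") <- list(params = params, beat_starts = starts,
                             period_factors = factors,
                             pf_true = pf, pb_true = pb)
  rec
}

#' Heart-failure progression presets
#'
#' Parameter sets emulating the three study arms of a rapid-ventricular-pacing
#' canine heart-failure progression: heart rate and stroke volume follow the
#' reported means (86.5/41.2, 99.1/28.0, 120.9/20.8 bpm / mL), the reflection
#' coefficient follows the reported reflection-magnitude means
#' (0.48, 0.39, 0.38), and the characteristic impedance is held constant at
#' 1.89 mmHg·min/L = 0.1134 mmHg·s/mL across stages (pacing leaves aortic Zc
#' unchanged). Ejection duration, reflection delay, diastolic pressure, and
#' time-to-peak-flow fraction shift in the directions expected for a dilating,
#' hypocontractile ventricle at higher heart rates.
#'
#' @param stage one of `"baseline"`, `"week1"`, `"month1"`.
#' @param ... overrides forwarded to [sim_params()] (e.g. `noise_sd_mmhg`,
#'   `seed`).
#' @return A [sim_params()] object.
#' @export
hf_preset <- function(stage, ...) {
  presets <- list(
    baseline = list(hr_bpm = 86.5, sv_ml = 41.2, gamma = 0.48, ed_ms = 230,
                    tau_ms = 70, frac_tp = 0.35, shape_a = 2,
                    dbp_mmhg = 72, tau_decay_ms = 350),
    week1 = list(hr_bpm = 99.1, sv_ml = 28.0, gamma = 0.39, ed_ms = 210,
                 tau_ms = 90, frac_tp = 0.44, shape_a = 4,
                 dbp_mmhg = 60, tau_decay_ms = 320),
    month1 = list(hr_bpm = 120.9, sv_ml = 20.8, gamma = 0.38, ed_ms = 180,
                  tau_ms = 85, frac_tp = 0.50, shape_a = 5,
                  dbp_mmhg = 58, tau_decay_ms = 300)
  )
  if (!is.character(stage) || length(stage) != 1L || !stage %in% names(presets))
    stop(sprintf("unknown stage '%s'; valid stages: %s",
                 as.character(stage)[1], paste(names(presets), collapse = ", ")),
         call. = FALSE)
  args <- presets[[stage]]
  args$zc_true <- 0.1134  # 1.89 mmHg·min/L, constant across stages
  args$noise_sd_mmhg <- 0.5
  args$noise_sd_flow <- 2
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}
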