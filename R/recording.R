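#' Construct a waveform recording
#'
#' Canonical container for a uniformly sampled arterial pressure recording
#' with optional simultaneous aortic flow. Internal units are fixed: seconds,
#' mmHg, mL/s; all unit conversion happens at the I/O boundary
#' ([read_recording()] / [write_recording()]).
#'
#' @param t time grid in seconds, strictly increasing and uniform.
#' @param p pressure in mmHg, finite, same length as `t`.
#' @param q optional flow in mL/s, same length as `p`.
#' @param fs_hz sampling rate, Hz.
#' @param meta free-form list of labels (subject id, session label, ...).
#' @return A list of class `pw_recording`.
#' @export
recording <- function(t, p, q = NULL, fs_hz, meta = list()) {
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    stop("fs_hz must be a positive scalar", call. = FALSE)
  if (length(t) != length(p))
    stop("t and p must have the same length", call. = FALSE)
  if (!all(is.finite(p))) stop("pressure must be finite", call. = FALSE)
  dt <- diff(t)
  if (length(dt) && (any(dt <= 0) ||
      (max(dt) - min(dt)) > 1e-6 * stats::median(dt)))
    stop("time grid must be strictly increasing and uniform", call. = FALSE)
  if (!is.null(q) && length(q) != length(p))
    stop("flow must have the same length as pressure", call. = FALSE)
  structure(list(t = t, p = p, q = q, fs_hz = fs_hz, meta = meta),
            class = "pw_recording")
}

#' @export
print.pw_recording <- function(x, ...) {
  cat(sprintf("<pw_recording> %d samples @ %g Hz (%.2f s), flow %s\n",
              length(x$p), x$fs_hz, length(x$p) / x$fs_hz,
              if (is.null(x$q)) "absent" else "present"))
  invisible(x)
}

flow_unit_factors <- c("mL/s" = 1, "L/min" = 1000 / 60, "mL/min" = 1 / 60)

#' Convert a flow series to mL/s
#'
#' @param x flow values.
#' @param unit declared unit, one of `"mL/s"`, `"L/min"`, `"mL/min"`.
#' @return Flow in mL/s.
#' @export
flow_to_ml_s <- function(x, unit) {
  if (!is.character(unit) || length(unit) != 1L ||
      !unit %in% names(flow_unit_factors))
    stop(sprintf("unknown flow unit '%s'; supported: %s",
                 as.character(unit)[1],
                 paste(names(flow_unit_factors), collapse = ", ")),
         call. = FALSE)
  x * flow_unit_factors[[unit]]
}

#' Read a delimited waveform file
#'
#' Expects a comma-delimited text file with a header containing a time column
#' (seconds), a pressure column (mmHg) and optionally a flow column whose unit
#' is declared either in the column name suffix (`flow_mL_s`, `flow_L_min`,
#' `flow_mL_min`) or via `config$flow_unit`. Flow is converted to mL/s;
#' non-uniform sampling is rejected.
#'
#' @param path file path.
#' @param config optional list: `time`, `pressure`, `flow` column names,
#'   `flow_unit`, and `fs_hz` override.
#' @return A [recording()].
#' @export
read_recording <- function(path, config = list()) {
  df <- utils::read.csv(path, check.names = FALSE)
  tcol <- config$time %||% "time_s"
  pcol <- config$pressure %||% "pressure_mmHg"
  if (!tcol %in% names(df))
    stop(sprintf("schema error: missing time column '%s' in %s", tcol, path),
         call. = FALSE)
  if (!pcol %in% names(df))
    stop(sprintf("schema error: missing pressure column '%s' in %s", pcol, path),
         call. = FALSE)
  qcol <- config$flow
  if (is.null(qcol)) {
    hit <- grep("^flow", names(df), value = TRUE)
    if (length(hit) > 1L)
      stop(sprintf("schema error: multiple flow columns in %s", path), call. = FALSE)
    if (length(hit) == 1L) qcol <- hit
  } else if (!qcol %in% names(df)) {
    stop(sprintf("schema error: missing flow column '%s' in %s", qcol, path),
         call. = FALSE)
  }
  t <- df[[tcol]]
  dt <- diff(t)
  if (length(dt) && (any(dt <= 0) ||
      (max(dt) - min(dt)) > 1e-6 * stats::median(dt)))
    stop(sprintf("sampling error: non-uniform time grid in %s", path),
         call. = FALSE)
  fs <- config$fs_hz %||% (1 / stats::median(dt))
  q <- NULL
  if (!is.null(qcol)) {
    unit <- config$flow_unit %||% parse_flow_unit(qcol)
    q <- flow_to_ml_s(df[[qcol]], unit)
  }
  recording(t = t, p = df[[pcol]], q = q, fs_hz = fs,
            meta = list(path = path))
}

parse_flow_unit <- function(colname) {
  suffix <- sub("^flow_?", "", colname)
  unit <- switch(suffix,
                 "mL_s" = "mL/s", "ml_s" = "mL/s",
                 "L_min" = "L/min", "l_min" = "L/min",
                 "mL_min" = "mL/min", "ml_min" = "mL/min",
                 NULL)
  if (is.null(unit))
    stop(sprintf("unit error: cannot infer flow unit from column '%s'; declare config$flow_unit",
                 colname), call. = FALSE)
  unit
}

#' Write a recording to the canonical delimited format
#'
#' Writes `time_s,pressure_mmHg[,flow_<unit>]`. If the recording carries a
#' simulation `truth` attribute, a key-value sidecar with the generative
#' parameters can be written alongside.
#'
#' @param rec a [recording()].
#' @param path output CSV path.
#' @param flow_unit unit used for the flow column on disk.
#' @param truth_path optional sidecar path for generative ground truth.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, flow_unit = "mL/s", truth_path = NULL) {
  stopifnot(inherits(rec, "pw_recording"))
  df <- data.frame(time_s = rec$t, pressure_mmHg = rec$p)
  if (!is.null(rec$q)) {
    fac <- flow_unit_factors[[flow_unit]]
    if (is.null(fac)) stop(sprintf("unknown flow unit '%s'", flow_unit), call. = FALSE)
    colname <- paste0("flow_", gsub("/", "_", flow_unit))
    df[[colname]] <- rec$q / fac
  }
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  truth <- attr(rec, "truth")
  if (!is.null(truth_path) && !is.null(truth)) {
    pars <- truth$params
    keys <- names(pars)[vapply(pars, function(v) is.numeric(v) && length(v) == 1L, logical(1))]
    lines <- sprintf("%s=%.12g", keys, unlist(pars[keys]))
    lines <- c(lines, sprintf("beat_starts=%s",
                              paste(truth$beat_starts, collapse = ",")))
    writeLines(lines, truth_path)
  }
  invisible(path)
}

#' Convert hydraulic power from mmHg·mL/s to microwatts
#'
#' 1 mmHg = 133.322 Pa and 1 mL/s = 1e-6 m3/s, so 1 mmHg·mL/s = 133.322 uW.
#'
#' @param x power in mmHg·mL/s.
#' @return Power in uW.
#' @export
convert_power_units <- function(x) x * 133.322

#' Characteristic impedance unit conversions
#'
#' `zc_to_mmhg_min_per_l()` converts mmHg·s/mL to the conventional reporting
#' unit mmHg·min/L (multiply by 1000/60); `zc_from_mmhg_min_per_l()` inverts
#' it.
#'
#' @param zc impedance value (positive).
#' @return Converted impedance.
#' @export
zc_to_mmhg_min_per_l <- function(zc) {
  stopifnot(zc > 0)
  zc * 1000 / 60
}

#' @rdname zc_to_mmhg_min_per_l
#' @export
zc_from_mmhg_min_per_l <- function(zc) {
  stopifnot(zc > 0)
  zc * 60 / 1000
}
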