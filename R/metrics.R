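#' Per-cycle summary metrics
#'
#' Computes the standard hemodynamic summary of the last complete cycle of
#' a trace: end-diastolic and end-systolic left-ventricular volume (cycle
#' max/min), stroke volume `sv = edv - esv`, cardiac output `co = sv * hr`,
#' ejection fraction `ef = sv / edv`, aortic systolic/diastolic pressure
#' (cycle max/min), pulse pressure, and the diastolic heart fraction of the
#' electrical timing attached to the trace.
#'
#' @param trace a `cardio_trace` spanning at least one complete cycle at
#'   steady state.
#' @param hr heart rate of the trace, min^-1 (default: trace attribute).
#' @return a `summary_metrics` list: `edv`, `esv`, `sv` (ml), `co`
#'   (ml/min), `ef`, `psys`, `pdia`, `pulse_pressure` (mmHg), `dhf`, `hr`.
#' @export
cycle_metrics <- function(trace, hr = attr(trace, "hr")) {
  if (is.null(hr)) metrics_error("heart rate unknown: pass hr explicitly")
  need <- c("time_s", "lv_volume_ml", "aorta_pressure_mmHg")
  miss <- setdiff(need, names(trace))
  if (length(miss)) {
    metrics_error(paste("trace lacks column(s):", paste(miss, collapse = ", ")))
  }
  dt <- attr(trace, "dt")
  if (is.null(dt)) dt <- stats::median(diff(trace$time_s))
  rr <- 60 / hr
  n_cyc <- max(1L, as.integer(round(rr / dt)))
  if (nrow(trace) < n_cyc) {
    metrics_error(sprintf(
      "trace (%d samples) shorter than one cycle (%d samples at hr = %g)",
      nrow(trace), n_cyc, hr))
  }
  cyc <- trace[seq.int(nrow(trace) - n_cyc + 1L, nrow(trace)), ]
  edv <- max(cyc$lv_volume_ml)
  esv <- min(cyc$lv_volume_ml)
  if (edv - esv < 1e-9) {
    metrics_error("no cardiac cycle detectable: left-ventricular volume is constant")
  }
  sv <- edv - esv
  timing <- attr(trace, "timing")
  structure(list(
    edv = edv, esv = esv, sv = sv,
    co = sv * hr, ef = sv / edv,
    psys = max(cyc$aorta_pressure_mmHg),
    pdia = min(cyc$aorta_pressure_mmHg),
    pulse_pressure = max(cyc$aorta_pressure_mmHg) - min(cyc$aorta_pressure_mmHg),
    dhf = if (!is.null(timing)) timing$dhf else NA_real_,
    hr = hr
  ), class = "summary_metrics")
}

# Zero-output summary for a converged cycle with constant ventricular
# volume (e.g. zero preload): sv = co = ef = 0 by definition.
degenerate_metrics <- function(trace, sim) {
  v <- trace$lv_volume_ml[nrow(trace)]
  structure(list(
    edv = v, esv = v, sv = 0, co = 0, ef = 0,
    psys = max(trace$aorta_pressure_mmHg),
    pdia = min(trace$aorta_pressure_mmHg),
    pulse_pressure = max(trace$aorta_pressure_mmHg) - min(trace$aorta_pressure_mmHg),
    dhf = sim$cache$timing$dhf,
    hr = sim$params$hr
  ), class = "summary_metrics")
}

#' @export
print.summary_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<summary_metrics> hr %g min^-1\n",
    "  EDV %.1f ml  ESV %.1f ml  SV %.1f ml  EF %.2f\n",
    "  CO %.0f ml/min  BP %.0f/%.0f mmHg  pulse pressure %.0f mmHg  DHF %.2f\n"),
    x$hr, x$edv, x$esv, x$sv, x$ef, x$co, x$psys, x$pdia, x$pulse_pressure, x$dhf))
  invisible(x)
}

#' Atrial contribution to cardiac output
#'
#' Runs the closed loop to steady state twice — once normally and once with
#' atrial contraction disabled (atrial maximal elastance reduced to its
#' passive minimum, so the atria become passive conduits) — and returns the
#' relative cardiac-output gain from atrial contraction in percent:
#' `100 * (CO_with - CO_without) / CO_without`. The contribution grows with
#' heart rate, as the atrial kick matters most when the diastolic filling
#' window is short, and stays below 10% with the shipped constants.
#'
#' @param params a `cardio_parameters` set with `model = "CCL"`.
#' @param settings [run_settings()].
#' @param constants [internal_constants()].
#' @return the contribution, percent.
#' @export
atrial_contribution <- function(params, settings = run_settings(),
                                constants = internal_constants()) {
  if (params$model != "CCL") model_error("atrial_contribution requires model = 'CCL'")
  co_with <- run_to_steady_state(params, settings, constants)$metrics$co
  co_without <- run_to_steady_state(params, settings,
                                    disable_atria(constants))$metrics$co
  100 * (co_with - co_without) / co_without
}

#' Disable atrial contraction in a constants set
#'
#' Returns a copy of the constants with both atrial maximal elastances set
#' equal to their minimal elastances, so the atria never actively contract.
#'
#' @param constants [internal_constants()].
#' @return modified `cardio_constants`.
#' @export
disable_atria <- function(constants = internal_constants()) {
  constants$chambers$la$e_max_ref <- constants$chambers$la$e_min
  constants$chambers$ra$e_max_ref <- constants$chambers$ra$e_min
  validate_constants(unclass(constants))
}

#' Animation geometry: atrioventricular-plane displacement
#'
#' Partitions the left-ventricular volume change over a cycle between
#' longitudinal shortening (displacement of the atrioventricular plane) and
#' radial contraction, using a cylinder model `V = pi * r^2 * L`. A
#' fraction `f_long` of every volume change from end-diastole is attributed
#' to length change measured at the end-diastolic radius; the radius then
#' follows from the instantaneous volume. With the default `f_long = 0.6`,
#' longitudinal shortening accounts for 60% of the stroke volume. Lengths
#' are arbitrary units (the rendered view is schematic).
#'
#' @param lv_volume left-ventricular volume over (at least) one cycle, ml.
#' @param f_long fraction of volume change via longitudinal shortening,
#'   in (0, 1).
#' @param reference_shape list with `length_diameter_ratio`: cylinder
#'   length over diameter at end-diastole.
#' @param time optional time stamps, s.
#' @return an `avpd_frames` data.frame: `t`, `lv_volume_ml`, `lv_length`,
#'   `lv_radius`, `avpd_displacement`, with the end-diastolic geometry and
#'   `f_long` as attributes.
#' @export
avpd_geometry <- function(lv_volume, f_long = 0.6,
                          reference_shape = list(length_diameter_ratio = 1.5),
                          time = NULL) {
  if (f_long <= 0 || f_long >= 1) {
    validation_error("f_long must lie strictly inside (0, 1)", fields = "f_long")
  }
  if (is.null(time)) time <- seq_along(lv_volume) - 1
  k <- reference_shape$length_diameter_ratio
  v_edv <- max(lv_volume)
  r_edv <- (v_edv / (2 * pi * k))^(1 / 3)  # V = pi r^2 L, L = 2 k r
  l_edv <- 2 * k * r_edv
  dv <- v_edv - lv_volume
  l_t <- l_edv - f_long * dv / (pi * r_edv^2)
  r_t <- sqrt(lv_volume / (pi * l_t))
  frames <- data.frame(
    t = time,
    lv_volume_ml = lv_volume,
    lv_length = l_t,
    lv_radius = r_t,
    avpd_displacement = l_edv - l_t
  )
  attr(frames, "f_long") <- f_long
  attr(frames, "r_edv") <- r_edv
  attr(frames, "l_edv") <- l_edv
  class(frames) <- c("avpd_frames", "data.frame")
  frames
}

#' Longitudinal share of the stroke volume
#'
#' From [avpd_geometry()] frames, the percentage of the stroke volume
#' accounted for by atrioventricular-plane (length) shortening, measured at
#' the end-diastolic radius: `100 * pi * r_edv^2 * max(avpd) / sv`.
#'
#' @param frames an `avpd_frames` object covering a full cycle.
#' @return percent of stroke volume; `NA` if the volume never changes.
#' @export
avpd_longitudinal_share <- function(frames) {
  sv <- max(frames$lv_volume_ml) - min(frames$lv_volume_ml)
  if (sv < 1e-12) return(NA_real_)
  r_edv <- attr(frames, "r_edv")
  100 * pi * r_edv^2 * max(frames$avpd_displacement) / sv
}

summary_units <- c(
  edv = "edv_ml", esv = "esv_ml", sv = "sv_ml", co = "co_ml_min",
  ef = "ef", psys = "psys_mmHg", pdia = "pdia_mmHg",
  pulse_pressure = "pulse_pressure_mmHg", dhf = "dhf", hr = "hr_min"
)

#' Write and read summary metrics as JSON
#'
#' Keys carry unit suffixes (`edv_ml`, `co_ml_min`, `psys_mmHg`, ...). All
#' fields of [cycle_metrics()] must be present; writing fails naming any
#' missing field. The pair round-trips losslessly.
#'
#' @param metrics a `summary_metrics` object.
#' @param path file path.
#' @return `export_summary()` returns `path` invisibly; `read_summary()`
#'   returns a `summary_metrics` object.
#' @export
export_summary <- function(metrics, path) {
  miss <- setdiff(names(summary_units), names(metrics))
  if (length(miss)) {
    metrics_error(paste("summary is missing field(s):", paste(miss, collapse = ", ")))
  }
  x <- stats::setNames(unclass(metrics)[names(summary_units)],
                       unname(summary_units))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname export_summary
#' @export
read_summary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  miss <- setdiff(unname(summary_units), names(x))
  if (length(miss)) {
    metrics_error(paste("summary file is missing key(s):", paste(miss, collapse = ", ")))
  }
  structure(stats::setNames(as.list(as.numeric(x[unname(summary_units)])),
                            names(summary_units)),
            class = "summary_metrics")
}
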