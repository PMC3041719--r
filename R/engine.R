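#' Run settings
#'
#' @param duration run length, s.
#' @param record_every record every k-th step (1 = every step).
#' @param steady_state_tol cycle-to-cycle end-diastolic-volume change (ml)
#'   below which the run counts as settled.
#' @param max_cycles cycle budget for [run_to_steady_state()].
#' @return a `run_settings` list.
#' @export
run_settings <- function(duration = 30, record_every = 1L,
                         steady_state_tol = 0.1, max_cycles = 200L) {
  if (duration <= 0) validation_error("duration must be > 0", fields = "duration")
  if (record_every < 1) validation_error("record_every must be >= 1",
                                         fields = "record_every")
  structure(list(duration = duration, record_every = as.integer(record_every),
                 steady_state_tol = steady_state_tol,
                 max_cycles = as.integer(max_cycles)),
            class = "run_settings")
}

# Per-cycle cache: electrical timing, trigger schedule, activation table and
# ECG template sampled at dt. The cycle is quantized to a whole number of
# steps; the quantization error in effective rate is at most dt/(2*rr).
cycle_cache <- function(model, hr, constants) {
  timing <- ecg_timing(hr, constants$ecg_coefficients,
                       constants$electromechanical_delay)
  triggers <- trigger_schedule(timing, constants$electromechanical_delay)
  dt <- constants$dt
  spc <- max(1L, as.integer(round(timing$rr / dt)))
  ts <- (seq_len(spc) - 1) * dt
  n <- length(model$ids)
  act <- matrix(0, nrow = spc, ncol = n)
  for (i in seq_len(n)) {
    if (model$kind[i] != KIND_CHAMBER) next
    if (identical(model$role[i], "atrium")) {
      act[, i] <- chamber_activation(ts, triggers$atrial_onset,
                                     triggers$systolic_duration_atrial)
    } else {
      act[, i] <- chamber_activation(ts, triggers$ventricular_onset,
                                     triggers$systolic_duration_ventricular)
    }
  }
  list(timing = timing, triggers = triggers, steps_per_cycle = spc,
       act = act, ecg = ecg_amplitude(ts, timing))
}

#' Create a simulation
#'
#' Builds the circulation network for the chosen model, the electrical
#' cycle cache for the configured heart rate, and the initial state. The
#' simulation is fully deterministic: no randomness enters anywhere, so
#' identical inputs give bit-identical traces.
#'
#' @param params a validated [default_parameters()] set.
#' @param constants [internal_constants()].
#' @param settings [run_settings()].
#' @return a `cardio_sim` object; advance it with [advance_simulation()],
#'   adjust it live with [set_parameter()], extract the recording with
#'   [sim_trace()].
#' @export
new_simulation <- function(params, constants = internal_constants(),
                           settings = run_settings()) {
  validate_parameters(params)
  model <- if (params$model == "IHL") build_ihl(params, constants)
           else build_ccl(params, constants)
  cache <- cycle_cache(model, params$hr, constants)
  structure(list(
    model = model, params = params, constants = constants,
    settings = settings,
    V = model$v_init, t = 0, gstep = 0L, step_in_cycle = 0L,
    pending_hr = NA_real_, cache = cache,
    recorded = list()
  ), class = "cardio_sim")
}

#' @export
print.cardio_sim <- function(x, ...) {
  cat(sprintf("<cardio_sim> %s at t = %.3f s, hr = %g min^-1\n",
              x$model$model_type, x$t, x$params$hr))
  invisible(x)
}

#' Advance a simulation
#'
#' Steps the network forward by `duration` seconds at the fixed step size,
#' recording the state every `record_every` steps. A pending heart-rate
#' change (see [set_parameter()]) is applied when the current electrical
#' cycle completes.
#'
#' @param sim a `cardio_sim`.
#' @param duration time to advance, s.
#' @param record logical; record the trace while advancing.
#' @return the updated `cardio_sim`.
#' @export
advance_simulation <- function(sim, duration, record = TRUE) {
  dt <- sim$constants$dt
  n_total <- as.integer(round(duration / dt))
  m <- sim$model
  while (n_total > 0) {
    if (sim$step_in_cycle == 0L && !is.na(sim$pending_hr)) {
      sim$params$hr <- sim$pending_hr
      sim$pending_hr <- NA_real_
      sim$cache <- cycle_cache(m, sim$params$hr, sim$constants)
    }
    chunk <- min(sim$cache$steps_per_cycle - sim$step_in_cycle, n_total)
    out <- simulate_chunk(
      sim$V, sim$gstep, sim$step_in_cycle,
      m$kind, m$e_min, m$e_max_eff, m$v0, m$compliance, m$v_unstressed,
      m$p_fixed, m$up, m$dn, m$resistance, m$is_valve,
      sim$cache$act, sim$cache$ecg,
      dt, chunk, sim$settings$record_every, record
    )
    if (record && out$rec_rows > 0) {
      sim$recorded[[length(sim$recorded) + 1L]] <-
        out$rec[seq_len(out$rec_rows), , drop = FALSE]
    }
    sim$V <- stats::setNames(out$V, m$ids)
    sim$gstep <- as.integer(out$gstep)
    sim$t <- out$t
    sim$step_in_cycle <- as.integer(out$step_in_cycle)
    if (out$err_comp > 0) {
      stability_error(sprintf(
        "negative volume in compartment '%s' at t = %.4f s; reduce dt",
        m$ids[out$err_comp], out$t))
    }
    n_total <- n_total - out$steps_done
  }
  sim
}

#' Extract the recorded trace of a simulation
#'
#' @param sim a `cardio_sim` that has been advanced with recording on.
#' @return a `cardio_trace` data.frame: `time_s`, one `<id>_volume_ml`
#'   column per volume-storing compartment, one `<id>_pressure_mmHg` per
#'   compartment, one `<id>_flow_ml_s` per connector, and `ecg_au`.
#'   Attributes `hr`, `dt`, `timing` and `model_type` describe the run.
#' @export
sim_trace <- function(sim) {
  if (!length(sim$recorded)) metrics_error("simulation has no recorded trace")
  m <- sim$model
  rec <- do.call(rbind, sim$recorded)
  n <- length(m$ids)
  cols <- c("time_s",
            paste0(m$ids, "_volume_ml"),
            paste0(m$ids, "_pressure_mmHg"),
            paste0(m$conn_ids, "_flow_ml_s"),
            "ecg_au")
  colnames(rec) <- cols
  keep <- c(TRUE, m$kind != KIND_SOURCE, rep(TRUE, n + length(m$up) + 1L))
  tr <- as.data.frame(rec[, keep, drop = FALSE])
  attr(tr, "hr") <- sim$params$hr
  attr(tr, "dt") <- sim$constants$dt * sim$settings$record_every
  attr(tr, "timing") <- sim$cache$timing
  attr(tr, "model_type") <- m$model_type
  class(tr) <- c("cardio_trace", "data.frame")
  tr
}

#' Change a parameter of a live simulation
#'
#' Applies a new value of any user-facing parameter to a running
#' simulation without resetting state. Heart-rate changes take effect at
#' the next cycle boundary (the current electrical cycle completes); every
#' other parameter takes effect at the very next step. A blood-volume
#' change rescales all compartment volumes proportionally so the
#' conservation invariant holds at the new total.
#'
#' @param sim a `cardio_sim`.
#' @param name parameter name, one of the rows of [parameter_limits()].
#' @param value new value, inside the parameter's closed limits.
#' @return the updated `cardio_sim`.
#' @export
set_parameter <- function(sim, name, value) {
  lim <- parameter_limits()
  i <- match(name, lim$parameter)
  if (is.na(i)) {
    cardio_abort("cardiolab_unknown_parameter",
                 sprintf("unknown parameter '%s'; valid: %s", name,
                         paste(lim$parameter, collapse = ", ")))
  }
  if (!is.finite(value) || value < lim$min[i] || value > lim$max[i]) {
    validation_error(sprintf("%s = %g outside limits [%g, %g] %s",
                             name, value, lim$min[i], lim$max[i], lim$unit[i]),
                     fields = name)
  }
  model_type <- sim$model$model_type
  if (name == "cvp" && model_type != "IHL") {
    model_error("cvp applies to the IHL model only")
  }
  if (name %in% c("tlr", "blood_volume", "contractility_rv") && model_type != "CCL") {
    model_error(sprintf("%s applies to the CCL model only", name))
  }

  if (name == "hr") {
    sim$pending_hr <- value
    return(sim)
  }
  sim$params[[name]] <- value
  m <- sim$model
  switch(name,
    cvp = { m$p_fixed[m$ids == "venous_source"] <- value },
    contractility_lv = {
      sel <- m$ids == "lv"
      m$e_max_eff[sel] <- (value / 100) * m$e_max_ref[sel]
    },
    contractility_rv = {
      sel <- m$ids == "rv"
      m$e_max_eff[sel] <- (value / 100) * m$e_max_ref[sel]
    },
    tpr = { m$resistance[m$conn_ids == "tpr"] <- value },
    tlr = {
      m$resistance[m$conn_ids %in% c("tlr_proximal", "tlr_distal")] <- value / 2
    },
    compliance = { m$compliance[m$ids == "aorta"] <- value },
    blood_volume = {
      total_new <- value * 1000
      sim$V <- sim$V * (total_new / sum(sim$V))
    }
  )
  sim$model <- m
  sim
}

#' Run a model for a fixed duration
#'
#' Convenience wrapper: build a simulation, advance it, return the trace.
#'
#' @inheritParams new_simulation
#' @return a `cardio_trace`, see [sim_trace()].
#' @examples
#' \donttest{
#' tr <- run_model(default_parameters("IHL"), run_settings(duration = 5))
#' head(tr[, 1:4])
#' }
#' @export
run_model <- function(params, settings = run_settings(),
                      constants = internal_constants()) {
  sim <- new_simulation(params, constants, settings)
  sim <- advance_simulation(sim, settings$duration, record = TRUE)
  sim_trace(sim)
}

#' Run to steady state
#'
#' Advances cycle by cycle until the end-diastolic volume of the left
#' ventricle (and of the right ventricle in the closed loop) changes by
#' less than `steady_state_tol` ml between consecutive cycles.
#'
#' @inheritParams new_simulation
#' @return a list: `trace` (the converged cycle), `cycle` (1-based index of
#'   the first converged cycle), `metrics` ([cycle_metrics()] of that
#'   cycle) and `sim` (the simulation, positioned at the start of the next
#'   cycle).
#' @export
run_to_steady_state <- function(params, settings = run_settings(),
                                constants = internal_constants()) {
  if (settings$max_cycles < 3) {
    validation_error("max_cycles must be >= 3", fields = "max_cycles")
  }
  sim <- new_simulation(params, constants, settings)
  track_rv <- params$model == "CCL"
  edv_prev <- NULL
  delta <- NA_real_
  for (k in seq_len(settings$max_cycles)) {
    sim$recorded <- list()
    sim <- advance_simulation(sim, sim$cache$steps_per_cycle * constants$dt,
                              record = TRUE)
    tr <- sim_trace(sim)
    edv <- c(lv = max(tr$lv_volume_ml),
             rv = if (track_rv) max(tr$rv_volume_ml) else NA_real_)
    if (!is.null(edv_prev)) {
      delta <- max(abs(edv - edv_prev), na.rm = TRUE)
      if (delta < settings$steady_state_tol) {
        # a settled heart with no preload pumps nothing: report a zero-output
        # cycle rather than failing on the flat volume trace
        met <- tryCatch(
          cycle_metrics(tr, hr = sim$params$hr),
          cardiolab_metrics_error = function(e) degenerate_metrics(tr, sim)
        )
        return(list(trace = tr, cycle = k, metrics = met, sim = sim))
      }
    }
    edv_prev <- edv
  }
  convergence_error(sprintf(
    "no steady state within %d cycles (last EDV change %.4g ml, tolerance %g ml)",
    settings$max_cycles, delta, settings$steady_state_tol), edv_delta = delta)
}

#' Steady-state parameter sweep
#'
#' Runs the model to steady state once per value of the swept parameter
#' (each point from a fresh simulation — no hysteresis between points) and
#' collects per-cycle summary metrics.
#'
#' @inheritParams new_simulation
#' @param sweep_param name of the parameter to sweep.
#' @param values numeric vector of values, each inside the limits.
#' @param metrics character vector of [cycle_metrics()] fields to keep;
#'   `NULL` keeps all.
#' @return a data.frame: the swept parameter first, then one column per
#'   metric, one row per value.
#' @export
sweep_parameter <- function(params, sweep_param, values, metrics = NULL,
                            settings = run_settings(),
                            constants = internal_constants()) {
  rows <- lapply(values, function(v) {
    p <- params
    p[[sweep_param]] <- v
    validate_parameters(p)
    ss <- run_to_steady_state(p, settings, constants)
    met <- unclass(ss$metrics)
    if (!is.null(metrics)) met <- met[metrics]
    met <- met[setdiff(names(met), sweep_param)]
    as.data.frame(c(stats::setNames(list(v), sweep_param), met))
  })
  do.call(rbind, rows)
}

#' Export a trace to CSV
#'
#' @param trace a `cardio_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Pressure-volume loop plot
#'
#' Plots left-ventricular pressure against volume for the recorded trace
#' (base graphics).
#'
#' @param x a `cardio_trace`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cardio_trace <- function(x, ...) {
  graphics::plot(x$lv_volume_ml, x$lv_pressure_mmHg, type = "l",
                 xlab = "LV volume (ml)", ylab = "LV pressure (mmHg)", ...)
  invisible(x)
}
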