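#' Rate-dependent ECG interval coefficients
#'
#' Each electrical interval is modelled as a quadratic function of cycle
#' length: `x = a + b*rr + c*rr^2` with `rr = 60/hr` in seconds. The
#' defaults are anchored to resting adult values at `rr = 1 s` (P duration
#' 0.09 s, PR 0.16 s, QRS 0.09 s, QT 0.40 s), with the rate dependence
#' concentrated in the QT interval, whose quadratic approximates the
#' square-root rate correction over the supported 40-160 min^-1 range. The
#' coefficient table is configuration: substitute published second-order
#' terms by passing a different table to [ecg_timing()] or
#' [internal_constants()].
#'
#' @return a named list with elements `p_dur`, `pr`, `qrs`, `qt`, each a
#'   numeric vector `c(a, b, c)`.
#' @export
default_ecg_coefficients <- function() {
  list(
    p_dur = c(0.07, 0.02, 0),
    pr    = c(0.10, 0.06, 0),
    qrs   = c(0.09, 0.00, 0),
    qt    = c(0.1272, 0.3357, -0.0629) # qt(rr = 1) = 0.4000 s
  )
}

eval_quad <- function(co, rr) co[1] + co[2] * rr + co[3] * rr^2

#' Electrical cycle timing for a heart rate
#'
#' Computes the interval set of one electrical cycle at a fixed heart rate:
#' cycle length `rr = 60/hr`, P-wave duration, PR interval (P onset to QRS
#' onset), QRS duration and QT interval (QRS onset to T end), each from its
#' quadratic coefficient row, plus the diastolic heart fraction
#' `dhf = 1 - (delay + qt)/rr` — the fraction of the cycle the ventricle
#' spends in mechanical diastole, which shrinks as the rate rises.
#'
#' @param hr heart rate, min^-1, in \[40, 160\].
#' @param coeffs coefficient table, see [default_ecg_coefficients()].
#' @param delay electromechanical delay, s.
#' @return an `ecg_timing` list: `hr`, `rr`, `p_dur`, `pr`, `qrs`, `qt`,
#'   `dhf` (all durations in seconds).
#' @examples
#' ecg_timing(70)$rr          # 60/70 s
#' ecg_timing(60)$qt          # 0.40 s at a 1-s cycle
#' @export
ecg_timing <- function(hr, coeffs = default_ecg_coefficients(), delay = 0.02) {
  if (length(hr) != 1 || !is.finite(hr) || hr < 40 || hr > 160) {
    validation_error(sprintf("hr = %g outside limits [40, 160] min^-1", hr),
                     fields = "hr")
  }
  rr <- 60 / hr
  t <- list(
    hr = hr,
    rr = rr,
    p_dur = eval_quad(coeffs$p_dur, rr),
    pr = eval_quad(coeffs$pr, rr),
    qrs = eval_quad(coeffs$qrs, rr),
    qt = eval_quad(coeffs$qt, rr)
  )
  t$dhf <- 1 - (delay + t$qt) / rr
  structure(t, class = "ecg_timing")
}

check_timing_invariants <- function(t) {
  ok <- t$p_dur > 0 && t$p_dur < t$pr && t$pr < t$rr &&
    t$qrs > 0 && t$qrs < t$qt && t$qt < t$rr &&
    t$dhf > 0 && t$dhf < 1 && (t$pr + t$qt) < t$rr
  ok
}

#' Validate an ECG coefficient table over the full heart-rate range
#'
#' Checks that the interval invariants (positive ordered intervals,
#' `pr + qt < rr`, diastolic fraction strictly inside (0, 1)) hold at every
#' integer heart rate from 40 to 160 min^-1. Called when constants are
#' constructed, so a bad table is rejected at load time rather than
#' mid-simulation.
#'
#' @inheritParams ecg_timing
#' @return `coeffs`, invisibly, if valid.
#' @export
validate_ecg_coefficients <- function(coeffs, delay = 0.02) {
  need <- c("p_dur", "pr", "qrs", "qt")
  if (!all(need %in% names(coeffs))) {
    config_error(sprintf("ecg coefficient table must name %s",
                         paste(need, collapse = ", ")))
  }
  for (hr in 40:160) {
    t <- ecg_timing(hr, coeffs, delay)
    if (!check_timing_invariants(t)) {
      config_error(sprintf(
        "ecg coefficients violate interval invariants at hr = %d (p_dur=%.3f pr=%.3f qrs=%.3f qt=%.3f rr=%.3f dhf=%.3f)",
        hr, t$p_dur, t$pr, t$qrs, t$qt, t$rr, t$dhf))
    }
  }
  invisible(coeffs)
}

# Waveform amplitude (arbitrary units) at time t within one cycle.
# Smooth unimodal P and T humps (sin^2), a triphasic Q-R-S complex built
# from contiguous half-sine lobes, exact zero baseline elsewhere. The T
# wave occupies the final 60% of the QRS-onset-to-T-end span so an
# isoelectric ST segment remains.
ecg_amplitude <- function(t, timing) {
  p_amp <- 0.15
  t_amp <- 0.30
  a <- numeric(length(t))

  # P wave on [0, p_dur]
  sel <- t >= 0 & t < timing$p_dur
  a[sel] <- p_amp * sin(pi * t[sel] / timing$p_dur)^2

  # QRS on [pr, pr + qrs]: Q (down), R (up), S (down) lobes
  u <- (t - timing$pr) / timing$qrs
  sel <- u >= 0 & u < 0.25
  a[sel] <- -0.15 * sin(pi * u[sel] / 0.25)
  sel <- u >= 0.25 & u < 0.7
  a[sel] <- 1.0 * sin(pi * (u[sel] - 0.25) / 0.45)
  sel <- u >= 0.7 & u < 1
  a[sel] <- -0.25 * sin(pi * (u[sel] - 0.7) / 0.3)

  # T wave: last 60% of [pr + qrs, pr + qt]
  t_width <- 0.6 * (timing$qt - timing$qrs)
  t_start <- timing$pr + timing$qt - t_width
  sel <- t >= t_start & t < timing$pr + timing$qt
  a[sel] <- t_amp * sin(pi * (t[sel] - t_start) / t_width)^2

  a
}

#' Synthesize one ECG cycle
#'
#' Assembles a single unscaled ECG cycle from parametric template fragments
#' time-scaled to the interval durations: a P wave on `[0, p_dur]`, a
#' triphasic QRS complex on `[pr, pr + qrs]`, a T wave ending at `pr + qt`,
#' and an exactly-zero baseline elsewhere. Amplitudes are fixed (arbitrary
#' units); the output carries timing information only.
#'
#' @param timing an [ecg_timing()] object.
#' @param resolution sample spacing, s; at most 0.001.
#' @return a data.frame with columns `time_s`, `ecg_au` covering one cycle
#'   `[0, rr)`.
#' @export
synthesize_ecg_cycle <- function(timing, resolution = 0.001) {
  if (resolution > 0.001 + 1e-12 || resolution <= 0) {
    validation_error("resolution must be positive and at most 0.001 s",
                     fields = "resolution")
  }
  tt <- seq(0, timing$rr - resolution / 2, by = resolution)
  data.frame(time_s = tt, ecg_au = ecg_amplitude(tt, timing))
}

#' Mechanical trigger schedule for one cycle
#'
#' Converts electrical timing into the onsets and durations of mechanical
#' contraction. Atrial contraction starts at the P onset plus the
#' electromechanical delay and lasts twice the P duration; ventricular
#' contraction starts at the QRS onset plus the delay and lasts 0.9 times
#' the QT interval (a small repolarisation margin is excluded).
#'
#' @param timing an [ecg_timing()] object.
#' @param delay electromechanical delay, s, >= 0.
#' @return a `trigger_schedule` list: `atrial_onset`, `ventricular_onset`,
#'   `systolic_duration_atrial`, `systolic_duration_ventricular` (s within
#'   the cycle).
#' @export
trigger_schedule <- function(timing, delay = 0.02) {
  if (delay < 0) validation_error("delay must be >= 0", fields = "delay")
  sch <- list(
    atrial_onset = delay,
    ventricular_onset = timing$pr + delay,
    systolic_duration_atrial = 2 * timing$p_dur,
    systolic_duration_ventricular = 0.9 * timing$qt
  )
  if (sch$ventricular_onset + sch$systolic_duration_ventricular >= timing$rr) {
    timing_error(sprintf(
      "ventricular systole (onset %.3f s + %.3f s) extends past cycle end (rr = %.3f s)",
      sch$ventricular_onset, sch$systolic_duration_ventricular, timing$rr))
  }
  if (sch$atrial_onset + sch$systolic_duration_atrial >= timing$rr) {
    timing_error("atrial systole extends past cycle end")
  }
  structure(sch, class = "trigger_schedule")
}
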