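#' Chamber activation waveform
#'
#' Normalised contraction activity of a chamber within one cycle: zero
#' outside the systolic window, a two-phase raised cosine inside it, rising
#' over the first 40% of the window and relaxing over the remaining 60%.
#' The waveform is continuous and reaches exactly 1 at its peak.
#'
#' @param t_in_cycle time since cycle start, s (vectorised).
#' @param onset systolic onset within the cycle, s.
#' @param duration systolic duration, s, > 0.
#' @return activation in \[0, 1\].
#' @examples
#' chamber_activation(0.3, onset = 0.18, duration = 0.3)  # peak = 1
#' @export
chamber_activation <- function(t_in_cycle, onset, duration) {
  if (duration <= 0) validation_error("duration must be > 0", fields = "duration")
  tau <- t_in_cycle - onset
  tau_peak <- 0.4 * duration
  a <- numeric(length(tau))
  rise <- tau >= 0 & tau <= tau_peak
  fall <- tau > tau_peak & tau <= duration
  a[rise] <- 0.5 * (1 - cos(pi * tau[rise] / tau_peak))
  a[fall] <- 0.5 * (1 + cos(pi * (tau[fall] - tau_peak) / (duration - tau_peak)))
  a
}

#' Instantaneous chamber pressure from the time-varying elastance model
#'
#' `P = E(a) * max(V - v0, 0)` with
#' `E(a) = e_min + a * (e_max_eff - e_min)` and
#' `e_max_eff = (contractility/100) * e_max_ref`. Contractility scales the
#' end-systolic elastance only; the passive (diastolic) elastance `e_min`
#' is unaffected. Pressure is floored at zero below the unstressed volume
#' `v0` — the model has no suction.
#'
#' @param spec a list with `e_min`, `e_max_ref`, `v0` (see
#'   [internal_constants()]) and optionally `contractility` (percent,
#'   default 100).
#' @param volume chamber volume, ml.
#' @param activation activation in \[0, 1\], see [chamber_activation()].
#' @return pressure, mmHg.
#' @examples
#' lv <- internal_constants()$chambers$lv
#' chamber_pressure(lv, volume = 60, activation = 1)  # 2.5 * (60 - 10)
#' @export
chamber_pressure <- function(spec, volume, activation) {
  contractility <- if (is.null(spec$contractility)) 100 else spec$contractility
  e_max_eff <- (contractility / 100) * spec$e_max_ref
  e <- spec$e_min + activation * (e_max_eff - spec$e_min)
  e * pmax(volume - spec$v0, 0)
}

#' Flow through an ideal diode valve
#'
#' `q = max(p_up - p_down, 0) / resistance`: forward flow down the pressure
#' gradient through a small series resistance, zero flow on a reversed
#' gradient. Strictly unidirectional — no regurgitation in any state.
#'
#' @param p_up upstream pressure, mmHg.
#' @param p_down downstream pressure, mmHg.
#' @param resistance open-valve resistance, mmHg/(ml/s), > 0.
#' @return flow, ml/s, always >= 0.
#' @examples
#' valve_flow(10, 5, 0.005)   # 1000 ml/s
#' valve_flow(5, 10, 0.005)   # 0: valve shut
#' @export
valve_flow <- function(p_up, p_down, resistance = 0.005) {
  if (any(resistance <= 0)) validation_error("resistance must be > 0",
                                             fields = "resistance")
  pmax(p_up - p_down, 0) / resistance
}
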