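#' Internal model constants
#'
#' Constants of the simulator that are not user-facing physiology: chamber
#' elastance bounds and unstressed volumes, vessel compliances and
#' unstressed volumes, valve and venous resistances, the electromechanical
#' delay, the ECG interval coefficients, the step size, and the initial
#' distribution of blood over the closed-loop compartments.
#'
#' Values are fixed human-adult textbook-range choices, calibrated once so
#' that the default parameter set settles into a physiological operating
#' point (aortic pressure near 120/80 mmHg, cardiac output 4-6 l/min,
#' atrial contribution to cardiac output below 10%). They are exposed so
#' that tests are reproducible and so that alternative parameterisations
#' can be substituted.
#'
#' @param ... named overrides, merged recursively into the defaults. Nested
#'   lists (e.g. `chambers`, `vessels`, `ecg_coefficients`) may be
#'   overridden per element: `internal_constants(chambers = list(lv =
#'   list(e_max_ref = 3)))`.
#' @return a validated `cardio_constants` list with elements:
#' \describe{
#'   \item{dt}{step size, s (default 0.001).}
#'   \item{electromechanical_delay}{delay between electrical onset and
#'     mechanical activation, s.}
#'   \item{chambers}{per chamber (`lv`, `rv`, `la`, `ra`): `e_min`,
#'     `e_max_ref` (mmHg/ml) and unstressed volume `v0` (ml).}
#'   \item{vessels}{per vessel compartment: `compliance` (ml/mmHg) and
#'     `v_unstressed` (ml). The aortic compliance is the user parameter and
#'     is not listed here.}
#'   \item{resistances}{valve resistance and the fixed venous/proximal
#'     resistances (mmHg/(ml/s)).}
#'   \item{ecg_coefficients}{quadratic interval coefficients, see
#'     [ecg_timing()].}
#'   \item{ccl_volume_fractions}{initial fraction of total blood volume per
#'     closed-loop compartment; sums to 1.}
#' }
#' @export
internal_constants <- function(...) {
  defaults <- list(
    dt = 0.001,
    electromechanical_delay = 0.02,
    chambers = list(
      lv = list(e_min = 0.08, e_max_ref = 2.5, v0 = 10),
      rv = list(e_min = 0.04, e_max_ref = 0.6, v0 = 10),
      la = list(e_min = 0.35, e_max_ref = 0.80, v0 = 5),
      ra = list(e_min = 0.35, e_max_ref = 0.80, v0 = 5)
    ),
    vessels = list(
      aorta         = list(v_unstressed = 60),   # compliance = user parameter
      arterial_bed  = list(compliance = 0.5, v_unstressed = 400),
      systemic_veins = list(compliance = 60, v_unstressed = 2900),
      pulm_artery   = list(compliance = 4,  v_unstressed = 50),
      pulm_cap_bed  = list(compliance = 5,  v_unstressed = 100),
      pulm_veins    = list(compliance = 15, v_unstressed = 350)
    ),
    resistances = list(
      valve = 0.005,          # all four valves, fully open
      venous_systemic = 0.04, # systemic veins (or IHL source) into atrium
      venous_pulmonary = 0.04,
      aorta_proximal = 0.05   # aorta into distal arterial bed
    ),
    ecg_coefficients = default_ecg_coefficients(),
    ccl_volume_fractions = c(
      systemic_veins = 0.6665, ra = 0.0090, rv = 0.0163,
      pulm_artery = 0.0219, pulm_cap_bed = 0.0308, pulm_veins = 0.0947,
      la = 0.0154, lv = 0.0173, aorta = 0.0389, arterial_bed = 0.0892
    )
  )
  cst <- utils::modifyList(defaults, list(...))
  validate_constants(cst)
}

validate_constants <- function(cst) {
  if (!is.numeric(cst$dt) || length(cst$dt) != 1 || cst$dt <= 0) {
    config_error("dt must be a single positive number of seconds")
  }
  if (cst$electromechanical_delay < 0) {
    config_error("electromechanical_delay must be >= 0")
  }
  for (nm in names(cst$chambers)) {
    ch <- cst$chambers[[nm]]
    if (ch$e_min <= 0 || ch$e_max_ref <= 0 || ch$e_max_ref < ch$e_min) {
      config_error(sprintf("chamber '%s': need 0 < e_min <= e_max_ref", nm))
    }
    if (ch$v0 < 0) config_error(sprintf("chamber '%s': v0 must be >= 0", nm))
  }
  for (nm in names(cst$vessels)) {
    vs <- cst$vessels[[nm]]
    if (!is.null(vs$compliance) && vs$compliance <= 0) {
      config_error(sprintf("vessel '%s': compliance must be > 0", nm))
    }
    if (vs$v_unstressed < 0) {
      config_error(sprintf("vessel '%s': v_unstressed must be >= 0", nm))
    }
  }
  for (nm in names(cst$resistances)) {
    if (cst$resistances[[nm]] <= 0) {
      config_error(sprintf("resistance '%s' must be > 0", nm))
    }
  }
  fr <- cst$ccl_volume_fractions
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    config_error("ccl_volume_fractions must be non-negative and sum to 1")
  }
  validate_ecg_coefficients(cst$ecg_coefficients, cst$electromechanical_delay)
  structure(cst, class = "cardio_constants")
}
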