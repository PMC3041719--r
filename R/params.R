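#' User-facing physiological parameters
#'
#' The simulator exposes seven physiological inputs, each with a default
#' value and a closed validity interval. Out-of-range values are rejected
#' with an error (never silently clamped), so scripts learn the valid range
#' the same way an interactive user would.
#'
#' @section Parameters:
#' \describe{
#'   \item{cvp}{Central venous pressure of the constant-preload source
#'     (mmHg); isolated-heart model only.}
#'   \item{hr}{Heart rate (min^-1).}
#'   \item{contractility_lv, contractility_rv}{Ventricular contractility as
#'     percent of a reference inotropy; scales end-systolic elastance.
#'     The right-ventricular value is used by the closed-loop model only.}
#'   \item{tpr}{Total peripheral resistance (mmHg/(ml/s)).}
#'   \item{compliance}{Aortic compliance, dV/dP (ml/mmHg).}
#'   \item{tlr}{Total lung resistance (mmHg/(ml/s)); closed loop only.}
#'   \item{blood_volume}{Total circulating blood volume (litres); closed
#'     loop only.}
#' }
#'
#' @param model `"IHL"` (isolated heart, constant preload) or `"CCL"`
#'   (closed double circulation).
#' @return `default_parameters()` returns a `cardio_parameters` object (a
#'   named list) holding all seven fields at their defaults plus the model
#'   choice. Fields not applicable to the chosen model are present but
#'   ignored by the model builders.
#' @examples
#' p <- default_parameters("CCL")
#' p$hr
#' p$blood_volume
#' @export
default_parameters <- function(model = c("CCL", "IHL")) {
  model <- check_model(model)
  lim <- parameter_limits()
  p <- as.list(stats::setNames(lim$default, lim$parameter))
  p$model <- model
  structure(p, class = "cardio_parameters")
}

check_model <- function(model) {
  if (length(model) != 1 || !is.character(model) || !model %in% c("IHL", "CCL")) {
    model_error(sprintf(
      "unknown model '%s'; valid models are 'IHL' and 'CCL'",
      paste(as.character(model), collapse = ",")
    ))
  }
  model
}

#' Parameter table: defaults and limits
#'
#' One row per user-facing input: default value, closed min/max interval,
#' unit, and the model(s) in which the parameter takes effect.
#'
#' @return A data.frame with columns `parameter`, `default`, `min`, `max`,
#'   `unit`, `model`.
#' @export
parameter_limits <- function() {
  data.frame(
    parameter = c("cvp", "hr", "contractility_lv", "contractility_rv",
                  "tpr", "compliance", "tlr", "blood_volume"),
    default   = c(10,  70, 100, 100, 1.0, 1.5, 0.1, 5.2),
    min       = c(0,   40,  25,  25, 0.2, 0.5, 0.02, 3.0),
    max       = c(30, 160, 200, 200, 2.0, 2.0, 0.5,  6.4),
    unit      = c("mmHg", "min^-1", "%", "%", "mmHg/(ml/s)", "ml/mmHg",
                  "mmHg/(ml/s)", "l"),
    model     = c("IHL", "IHL/CCL", "IHL/CCL", "CCL", "IHL/CCL", "IHL/CCL",
                  "CCL", "CCL"),
    stringsAsFactors = FALSE
  )
}

#' Validate a parameter set against its limits
#'
#' Every field is checked against its closed interval; all violations are
#' reported together. Values are returned unchanged (validation never
#' clamps).
#'
#' @param params a `cardio_parameters` object or a named list with the same
#'   fields.
#' @return the input, invisibly unchanged, if valid.
#' @examples
#' p <- default_parameters("IHL")
#' p$hr <- 160            # boundary values are allowed
#' validate_parameters(p)
#' @export
validate_parameters <- function(params) {
  if (is.null(params$model)) model_error("parameter set has no 'model' field")
  check_model(params$model)
  lim <- parameter_limits()
  bad <- character()
  msgs <- character()
  for (i in seq_len(nrow(lim))) {
    nm <- lim$parameter[i]
    v <- params[[nm]]
    if (is.null(v) || length(v) != 1 || !is.finite(v)) {
      bad <- c(bad, nm)
      msgs <- c(msgs, sprintf("%s: missing or non-finite", nm))
      next
    }
    if (v < lim$min[i] || v > lim$max[i]) {
      bad <- c(bad, nm)
      msgs <- c(msgs, sprintf("%s = %g outside limits [%g, %g] %s",
                              nm, v, lim$min[i], lim$max[i], lim$unit[i]))
    }
  }
  if (length(bad)) {
    validation_error(
      paste0("invalid parameter value(s):\n  ", paste(msgs, collapse = "\n  ")),
      fields = bad
    )
  }
  params
}

#' @export
print.cardio_parameters <- function(x, ...) {
  cat(sprintf("<cardio_parameters> model = %s\n", x$model))
  lim <- parameter_limits()
  for (nm in lim$parameter) {
    cat(sprintf("  %-17s %8g %s\n", nm, x[[nm]],
                lim$unit[match(nm, lim$parameter)]))
  }
  invisible(x)
}

config_keys <- function() {
  c("model", "cvp", "hr", "contractility_lv", "contractility_rv",
    "tpr", "compliance", "tlr", "blood_volume")
}

#' Read a parameter configuration from a YAML file
#'
#' Recognised keys are exactly `model`, `cvp`, `hr`, `contractility_lv`,
#' `contractility_rv`, `tpr`, `compliance`, `tlr`, `blood_volume`. Keys not
#' present fall back to the defaults of [default_parameters()]; the merged
#' set must pass [validate_parameters()]. An empty file yields the full
#' default set.
#'
#' @param path path to a YAML file.
#' @return a validated `cardio_parameters` object.
#' @seealso [write_config()] for the inverse; the two round-trip.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) config_error(sprintf("cannot parse '%s': %s",
                                             path, conditionMessage(e)))
  )
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) config_error(sprintf("config '%s' is not a key/value mapping", path))
  unknown <- setdiff(names(raw), config_keys())
  if (length(unknown)) {
    config_error(sprintf("unknown config key(s): %s (valid keys: %s)",
                         paste(unknown, collapse = ", "),
                         paste(config_keys(), collapse = ", ")))
  }
  model <- if (!is.null(raw$model)) toupper(raw$model) else "CCL"
  params <- default_parameters(model)
  for (nm in setdiff(names(raw), "model")) params[[nm]] <- as.numeric(raw[[nm]])
  validate_parameters(params)
}

#' Write a parameter configuration to a YAML file
#'
#' @param params a `cardio_parameters` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  validate_parameters(params)
  x <- params[config_keys()]
  yaml::write_yaml(x, path)
  invisible(path)
}
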