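# Classed conditions used across the package so callers can distinguish
# user error (bad parameters, bad config) from numerical trouble.

cardio_abort <- function(class, message, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(class, "cardiolab_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

validation_error <- function(message, fields = character()) {
  cardio_abort("cardiolab_validation_error", message, fields = fields)
}

config_error <- function(message) cardio_abort("cardiolab_config_error", message)
model_error <- function(message) cardio_abort("cardiolab_model_error", message)
timing_error <- function(message) cardio_abort("cardiolab_timing_error", message)
stability_error <- function(message) cardio_abort("cardiolab_stability_error", message)
convergence_error <- function(message, edv_delta = NA_real_) {
  cardio_abort("cardiolab_convergence_error", message, edv_delta = edv_delta)
}
metrics_error <- function(message) cardio_abort("cardiolab_metrics_error", message)
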