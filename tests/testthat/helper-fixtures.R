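# Shared fixtures: everything is generated in code, no stored data.

# A synthetic one-cycle trace with known extrema, for metrics unit tests:
# LV volume swings 120 <-> 50 ml, aortic pressure 120 <-> 80 mmHg at 60/min.
synthetic_trace <- function(hr = 60, n = 1000) {
  tt <- seq(0, by = 0.001, length.out = n)
  tr <- data.frame(
    time_s = tt,
    lv_volume_ml = 85 + 35 * cos(2 * pi * tt),
    aorta_pressure_mmHg = 100 + 20 * sin(2 * pi * tt)
  )
  attr(tr, "hr") <- hr
  attr(tr, "dt") <- 0.001
  class(tr) <- c("cardio_trace", "data.frame")
  tr
}

# Single compliant tank draining through a resistor: the analytic RC test bed.
rc_tank_model <- function(C = 1, R = 1) {
  build_circulation(
    list(vessel_compartment("tank", compliance = C, v_unstressed = 0)),
    list(connector("drain", "tank", "sink", resistance = R))
  )
}

volume_columns <- function(trace) {
  as.matrix(trace[, grep("_volume_ml$", names(trace)), drop = FALSE])
}
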