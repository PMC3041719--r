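test_that("a run records duration/dt rows and is bit-identical on repeat", {
  p <- default_parameters("IHL")
  tr1 <- run_model(p, run_settings(duration = 1))
  expect_equal(nrow(tr1), 1000)
  expect_true(all(diff(tr1$time_s) > 0))
  tr2 <- run_model(p, run_settings(duration = 1))
  expect_identical(tr1, tr2)
  # thinned recording
  tr4 <- run_model(p, run_settings(duration = 1, record_every = 4))
  expect_equal(nrow(tr4), 250)
})

test_that("setting a parameter to its current value leaves the run unchanged", {
  p <- default_parameters("CCL")
  uninterrupted <- advance_simulation(new_simulation(p), 2)
  interrupted <- advance_simulation(new_simulation(p), 1)
  interrupted <- set_parameter(interrupted, "tpr", p$tpr)
  interrupted <- advance_simulation(interrupted, 1)
  expect_identical(sim_trace(uninterrupted), sim_trace(interrupted))
})

test_that("raising afterload mid-run raises aortic pressure over later cycles", {
  p <- default_parameters("CCL")
  sim <- advance_simulation(new_simulation(p), 1)
  sim <- set_parameter(sim, "tpr", 2.0)
  sim <- advance_simulation(sim, 5)
  tr <- sim_trace(sim)
  before <- mean(tr$aorta_pressure_mmHg[tr$time_s < 1])
  after <- mean(tr$aorta_pressure_mmHg[tr$time_s > 5])
  expect_gt(after, before + 10)
})

test_that("heart-rate changes wait for the cycle boundary", {
  p <- default_parameters("CCL")  # rr = 60/70, quantized to 857 steps
  changed <- advance_simulation(new_simulation(p), 0.3)
  changed <- set_parameter(changed, "hr", 120)
  changed <- advance_simulation(changed, 1.5)
  plain <- advance_simulation(new_simulation(p), 1.8)
  tr_c <- sim_trace(changed)
  tr_p <- sim_trace(plain)
  boundary <- 0.857
  same <- tr_c$time_s < boundary
  expect_identical(as.matrix(tr_c[same, ]), as.matrix(tr_p[same, ]))
  # after the boundary the cycles differ (new electrical cycle length)
  expect_false(isTRUE(all.equal(tr_c$ecg_au[!same], tr_p$ecg_au[!same])))
  expect_equal(changed$params$hr, 120)
})

test_that("mid-run parameter changes conserve total volume; blood volume rescales", {
  p <- default_parameters("CCL")
  sim <- advance_simulation(new_simulation(p), 1, record = FALSE)
  total_before <- sum(sim$V)
  sim <- set_parameter(sim, "tpr", 1.7)
  sim <- set_parameter(sim, "contractility_lv", 150)
  expect_identical(sum(sim$V), total_before)
  shares <- sim$V / sum(sim$V)
  sim <- set_parameter(sim, "blood_volume", 4.0)
  expect_equal(sum(sim$V), 4000, tolerance = 1e-9)
  expect_equal(unname(sim$V / sum(sim$V)), unname(shares), tolerance = 1e-12)
})

test_that("parameter names and limits are enforced on live changes", {
  sim <- new_simulation(default_parameters("CCL"))
  expect_error(set_parameter(sim, "afterload", 1),
               class = "cardiolab_unknown_parameter")
  expect_error(set_parameter(sim, "hr", 200),
               class = "cardiolab_validation_error")
  expect_error(set_parameter(sim, "cvp", 10),
               class = "cardiolab_model_error")  # IHL-only parameter
})

test_that("steady state is reached and stays settled", {
  ihl <- run_to_steady_state(default_parameters("IHL"))
  expect_lte(ihl$cycle, 30)
  expect_s3_class(ihl$metrics, "summary_metrics")
  # with an infinite tolerance the second cycle counts as settled
  lax <- run_to_steady_state(default_parameters("IHL"),
                             run_settings(steady_state_tol = Inf))
  expect_equal(lax$cycle, 2)
  # closed loop: EDV stays within tolerance for 10 further cycles
  ccl <- run_to_steady_state(default_parameters("CCL"))
  sim <- ccl$sim
  edv <- max(ccl$trace$lv_volume_ml)
  for (k in 1:10) {
    sim$recorded <- list()
    sim <- advance_simulation(sim, sim$cache$steps_per_cycle * sim$constants$dt)
    edv_k <- max(sim_trace(sim)$lv_volume_ml)
    expect_lt(abs(edv_k - edv), 0.1)
    edv <- edv_k
  }
  # pathologically tight tolerance reports non-convergence with the delta
  err <- expect_error(
    run_to_steady_state(default_parameters("CCL"),
                        run_settings(steady_state_tol = 0, max_cycles = 5)),
    class = "cardiolab_convergence_error")
  expect_true(is.finite(err$edv_delta))
})

test_that("halving the step size barely moves the steady-state stroke volume", {
  p <- default_parameters("IHL")
  sv_1ms <- run_to_steady_state(p)$metrics$sv
  sv_05ms <- run_to_steady_state(p, constants = internal_constants(dt = 5e-4))$metrics$sv
  expect_lt(abs(sv_05ms - sv_1ms) / sv_1ms, 0.01)
})

test_that("sweeps run each point fresh and match single runs", {
  p <- default_parameters("IHL")
  one <- sweep_parameter(p, "hr", 90, metrics = c("sv", "co"))
  expect_equal(nrow(one), 1)
  ref <- run_to_steady_state({p$hr <- 90; p})$metrics
  expect_equal(one$sv, ref$sv)
  expect_equal(one$co, ref$co)
  multi <- sweep_parameter(default_parameters("IHL"), "hr", c(60, 100, 140))
  expect_equal(multi$hr, c(60, 100, 140), ignore_attr = TRUE)
  expect_true(all(diff(multi$sv) < 0))
})

test_that("trace export writes unit-suffixed headers", {
  tr <- run_model(default_parameters("IHL"), run_settings(duration = 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  export_trace(tr, path)
  hdr <- names(utils::read.csv(path, nrows = 1))
  expect_true(all(c("time_s", "lv_volume_ml", "lv_pressure_mmHg",
                    "aortic_valve_flow_ml_s", "ecg_au") %in% hdr))
})
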