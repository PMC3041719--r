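test_that("isolated-heart network has 5 compartments, 2 valves, user compliance", {
  p <- default_parameters("IHL")
  p$compliance <- 0.9
  m <- build_ihl(p)
  expect_length(m$ids, 5)
  expect_equal(sum(m$is_valve), 2)
  expect_setequal(m$conn_ids[m$is_valve], c("mitral_valve", "aortic_valve"))
  expect_equal(m$compliance[m$ids == "aorta"], 0.9)
  expect_equal(m$p_fixed[m$ids == "venous_source"], p$cvp)
  expect_error(build_ihl(default_parameters("CCL")),
               class = "cardiolab_model_error")
})

test_that("closed-loop network has 10 compartments, 4 valves, configured volume", {
  p <- default_parameters("CCL")
  m <- build_ccl(p)
  expect_length(m$ids, 10)
  expect_equal(sum(m$is_valve), 4)
  expect_setequal(m$conn_ids[m$is_valve],
                  c("tricuspid_valve", "pulmonary_valve", "mitral_valve",
                    "aortic_valve"))
  expect_equal(sum(m$v_init), 5200)
  # every connector endpoint is internal: the loop is closed
  expect_true(all(m$dn > 0))
  expect_error(build_ccl(default_parameters("IHL")),
               class = "cardiolab_model_error")
})

test_that("a gradient-free network does not move", {
  m <- build_circulation(
    list(vessel_compartment("a", compliance = 1, v_unstressed = 0),
         vessel_compartment("b", compliance = 2, v_unstressed = 0)),
    list(connector("ab", "a", "b", resistance = 0.1)))
  st <- initial_state(m)
  st$volumes[] <- c(a = 50, b = 100)  # both at 50 mmHg
  nxt <- circulation_step(m, st, dt = 0.001)
  expect_equal(nxt$t, 0.001)
  expect_identical(unname(nxt$volumes), c(50, 100))
  expect_identical(unname(nxt$flows), 0)
})

test_that("single steps conserve closed-loop volume exactly", {
  m <- build_ccl(default_parameters("CCL"))
  st <- initial_state(m)
  tm <- ecg_timing(70)
  trg <- trigger_schedule(tm)
  for (k in 1:50) st <- circulation_step(m, st, trg, dt = 0.001, rr = tm$rr)
  expect_equal(sum(st$volumes), 5200, tolerance = 1e-12)
  expect_true(all(st$volumes >= 0))
  expect_true(all(st$flows[m$is_valve] >= 0))
})

test_that("vessel discharge follows the analytic exponential decay", {
  m <- rc_tank_model(C = 1, R = 1)  # time constant 1 s
  st <- initial_state(m)
  st$volumes[] <- 100
  for (k in 1:1000) st <- circulation_step(m, st, dt = 0.001)
  expect_equal(st$volumes[["tank"]], 100 * exp(-1), tolerance = 0.005)
})

test_that("reference R step and compiled engine agree over a full cycle", {
  p <- default_parameters("IHL")
  p$hr <- 60  # 1-s cycle: an integer number of steps, no phase drift
  cst <- internal_constants()
  m <- build_ihl(p, cst)
  tm <- ecg_timing(60, cst$ecg_coefficients, cst$electromechanical_delay)
  trg <- trigger_schedule(tm, cst$electromechanical_delay)
  st <- initial_state(m)
  for (k in 1:1000) st <- circulation_step(m, st, trg, dt = cst$dt, rr = tm$rr)
  sim <- new_simulation(p, cst)
  sim <- advance_simulation(sim, 1, record = FALSE)
  expect_equal(unname(st$volumes[m$kind != 2L]),
               unname(sim$V[m$kind != 2L]), tolerance = 1e-9)
})

test_that("aortic valve carries flow exactly when the ventricle leads the aorta", {
  tr <- run_model(default_parameters("IHL"), run_settings(duration = 2))
  open <- tr$aortic_valve_flow_ml_s > 0
  gradient <- tr$lv_pressure_mmHg > tr$aorta_pressure_mmHg
  expect_identical(open, gradient)
  expect_true(any(open))          # it does eject
  expect_true(any(!open))         # and it does close in diastole
  expect_true(all(tr$aortic_valve_flow_ml_s >= 0))
  expect_true(all(tr$mitral_valve_flow_ml_s >= 0))
})

test_that("no corner of the parameter space loses volume or goes negative", {
  ihl <- expand.grid(cvp = c(0, 30), hr = c(40, 160), contractility_lv = c(25, 200),
                     tpr = c(0.2, 2), compliance = c(0.5, 2))
  for (i in seq_len(nrow(ihl))) {
    p <- default_parameters("IHL")
    for (nm in names(ihl)) p[[nm]] <- ihl[i, nm]
    tr <- run_model(p, run_settings(duration = 3))
    expect_gte(min(volume_columns(tr)), 0)
  }
  ccl <- expand.grid(hr = c(40, 160), contractility_lv = c(25, 200),
                     contractility_rv = c(25, 200), tpr = c(0.2, 2),
                     compliance = c(0.5, 2), tlr = c(0.02, 0.5),
                     blood_volume = c(3.0, 6.4))
  set.seed(42)
  for (i in sample(nrow(ccl), 16)) {
    p <- default_parameters("CCL")
    for (nm in names(ccl)) p[[nm]] <- ccl[i, nm]
    tr <- run_model(p, run_settings(duration = 3))
    expect_gte(min(volume_columns(tr)), 0)
    total <- rowSums(volume_columns(tr))
    expect_lt(max(abs(total - p$blood_volume * 1000)), 1e-6)
  }
})
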