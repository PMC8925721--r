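test_that("passive compartment matches the RC closed form", {
  m <- network_model(list(passive_single()),
                     injections = list(step_current(1, "S", -1, 100, 500)))
  r <- simulate_network(m, simulation_config(700, settle_time = 0))
  v <- voltage_trace(r, 1, "S")
  expect_equal(v[1], -75)
  # steady state dV = I / g_leak
  expect_equal(v[r$time == 590] - v[1], -10, tolerance = 1e-6)
  # exponential approach with tau = c_m / g_leak = 10 ms
  expect_equal(v[r$time == 110] - v[1], -10 * (1 - exp(-1)),
               tolerance = 1e-5)
})

test_that("trace length and time base follow duration/dt", {
  r <- simulate_network(network_model(list(passive_single())),
                        simulation_config(50, dt = 0.05, settle_time = 0))
  expect_equal(nrow(r$voltage), 50 / 0.05 + 1)
  expect_equal(r$time[1], 0)
  expect_equal(max(r$time), 50)
})

test_that("simulation is deterministic (bit-identical reruns)", {
  b <- make_burst(1, onset = 50)
  m <- network_model(list(make_three_compartment_trn()),
                     chemical = list(b$synapse), injections = list(b$holding))
  cfg <- simulation_config(200, settle_time = 100)
  r1 <- simulate_network(m, cfg)
  r2 <- simulate_network(m, cfg)
  expect_identical(r1$voltage, r2$voltage)
})

test_that("mirror-symmetric configurations are exactly exchange-symmetric", {
  cell <- make_three_compartment_trn()
  mk <- function(src) coupled_pair(c("M", "M"), 0.12, cell1 = cell,
                                   cell2 = cell,
                                   injections = list(
                                     step_current(src, "S", -0.5, 100, 300)))
  ra <- simulate_network(mk(1), simulation_config(500, settle_time = 100))
  rb <- simulate_network(mk(2), simulation_config(500, settle_time = 100))
  for (lab in c("S", "M", "D")) {
    expect_identical(voltage_trace(ra, 1, lab), voltage_trace(rb, 2, lab))
    expect_identical(voltage_trace(ra, 2, lab), voltage_trace(rb, 1, lab))
  }
})

test_that("halving dt leaves subthreshold trajectories unchanged to < 1e-3 mV", {
  m <- coupled_pair(c("S", "S"), 0.15,
                    injections = list(step_current(1, "S", -0.5, 100, 800)))
  rA <- simulate_network(m, simulation_config(1000, dt = 0.01))
  rB <- simulate_network(m, simulation_config(1000, dt = 0.005))
  expect_lt(max(abs(rA$voltage[nrow(rA$voltage), ] -
                      rB$voltage[nrow(rB$voltage), ])), 1e-3)
})

test_that("numerical blow-up aborts with a diagnostic naming the compartment", {
  m <- network_model(list(passive_single()),
                     injections = list(step_current(1, "S", 1e5, 0, Inf)))
  expect_error(simulate_network(m, simulation_config(10, settle_time = 0)),
               "blow-up.*compartment 1")
})

test_that("synapse and stimulus endpoints are validated", {
  cell <- make_single_compartment_trn()
  expect_error(network_model(list(cell, cell),
                             electrical = list(
                               electrical_synapse(1, "S", 2, "D", 0.1))),
               "missing compartment")
  expect_error(network_model(list(cell),
                             injections = list(step_current(2, "S", 1))),
               "missing cell")
})

test_that("spike detection matches a local-maximum oracle on tonic trains", {
  m <- network_model(list(make_single_compartment_trn()),
                     injections = list(step_current(1, "S", 0.7, 0, Inf)))
  r <- simulate_network(m, simulation_config(1500))
  v <- voltage_trace(r, 1, "S")
  sp <- detect_spikes(r)
  # oracle: count suprathreshold local maxima
  is_peak <- v[2:(length(v) - 1)] > 0 &
    v[2:(length(v) - 1)] >= v[1:(length(v) - 2)] &
    v[2:(length(v) - 1)] > v[3:length(v)]
  expect_equal(length(sp), sum(is_peak))
  expect_gt(length(sp), 10)
  # threshold-insensitivity across a wide band
  for (thr in c(-20, -10, 10)) {
    expect_equal(length(detect_spikes(v, dt = r$dt, threshold = thr)),
                 length(sp))
  }
})

test_that("spike detection handles flat and single-spike traces", {
  expect_identical(detect_spikes(rep(-75, 1000), dt = 0.01), numeric(0))
  # one brief strong somatic pulse evokes exactly one action potential
  m <- network_model(list(make_single_compartment_trn()),
                     injections = list(step_current(1, "S", 10, 20, 2)))
  r <- simulate_network(m, simulation_config(60))
  sp <- detect_spikes(r)
  expect_length(sp, 1)
  expect_gt(sp, 20)
})

test_that("trace CSV export carries time plus one column per compartment", {
  r <- simulate_network(coupled_pair(c("S", "S"), 0.1,
                                     cell1 = passive_single(),
                                     cell2 = passive_single()),
                        simulation_config(10, settle_time = 0))
  path <- tempfile(fileext = ".csv")
  write_traces_csv(r, path)
  d <- utils::read.csv(path, check.names = FALSE)
  expect_equal(names(d), c("time_ms", "cell1.S", "cell2.S"))
  expect_equal(nrow(d), length(r$time))
  expect_true(file.exists(paste0(path, ".manifest")))
  unlink(c(path, paste0(path, ".manifest")))
})
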