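gmax_of <- function(comp) {
  g <- vapply(comp$channels, `[[`, numeric(1), "g_max")
  g[order(match(names(g), CHANNEL_NAMES))]
}

test_that("single-compartment parameter table is exact", {
  cell <- make_single_compartment_trn()
  expect_length(cell$compartments, 1)
  soma <- cell$compartments$S
  expect_equal(gmax_of(soma),
               c(NaT = 60.5, Kd = 60, Kt = 5, K2 = 0.5, AR = 0.025,
                 CaT = 0.75))
  expect_equal(soma$c_m, 1)
  expect_equal(soma$g_leak, 0.1)
  expect_equal(soma$e_leak, -75)
})

test_that("three-compartment parameter table is exact", {
  cell <- make_three_compartment_trn()
  expect_named(cell$compartments, c("S", "M", "D"))
  expect_equal(gmax_of(cell$compartments$S),
               c(NaT = 60.5, Kd = 90, Kt = 5, K2 = 0.5, AR = 0.005,
                 CaT = 0.5))
  for (lab in c("M", "D")) {
    dend <- cell$compartments[[lab]]
    expect_false("NaT" %in% names(dend$channels))
    expect_equal(dend$channels$CaT$g_max, 0.15)
    expect_equal(dend$g_leak, 0.035)
    expect_equal(dend$c_m, 1.2)
  }
  expect_equal(cell$compartments$S$g_leak, 0.1)
  expect_equal(cell$compartments$S$c_m, 1.2)
  expect_equal(unname(cell$g_internal), c(0.4, 0.35))
  expect_named(cell$g_internal, c("S-M", "M-D"))
})

test_that("dendritic compartments refuse a sodium conductance", {
  expect_error(compartment_params("M", 1.2, 0.035,
                                  channels = c(NaT = 60.5)), "NaT")
  expect_silent(compartment_params("S", 1.2, 0.1, channels = c(NaT = 60.5)))
})

test_that("scale_leak multiplies leak only, and rejects bad factors", {
  cell <- make_three_compartment_trn()
  expect_equal(scale_leak(cell, 1), cell)
  up <- scale_leak(cell, 1.45)
  expect_equal(up$compartments$S$g_leak, 0.145)
  expect_equal(up$compartments$D$g_leak, 0.035 * 1.45)
  expect_equal(up$compartments$S$channels, cell$compartments$S$channels)
  expect_error(scale_leak(cell, 0), "positive")
  expect_error(scale_leak(cell, -1), "positive")
  # soma-only variant
  so <- scale_leak(cell, 2, compartments = "S")
  expect_equal(so$compartments$M$g_leak, 0.035)
  expect_equal(so$compartments$S$g_leak, 0.2)
})

test_that("input resistance moves opposite to the leak factor", {
  cell <- passive_three()
  r <- vapply(c(0.75, 1, 1.45), function(f)
    analytic_input_resistance(network_model(list(scale_leak(cell, f)))),
    numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("scale_internal multiplies the two internal conductances", {
  cell <- make_three_compartment_trn()
  expect_equal(scale_internal(cell, 1, 1), cell)
  sc <- scale_internal(cell, 0.867, 0.8)
  expect_equal(unname(sc$g_internal), c(0.4 * 0.867, 0.35 * 0.8))
  expect_error(scale_internal(cell, 0, 1), "positive")
})

test_that("cell config files round-trip", {
  cell <- scale_internal(make_three_compartment_trn(), 1.2, 1.2)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_cell_config(cell, path)
  back <- read_cell_config(path)
  expect_equal(unname(back$g_internal), unname(cell$g_internal))
  expect_equal(gmax_of(back$compartments$S), gmax_of(cell$compartments$S))
  expect_equal(back$compartments$D$g_leak, cell$compartments$D$g_leak)
})

test_that("models rest at a fixed point with no stimulus (regression values)", {
  r <- simulate_network(network_model(list(make_single_compartment_trn())),
                        simulation_config(1000))
  v <- voltage_trace(r, 1, "S")
  n <- length(v)
  expect_lt(abs(v[n] - v[n - 1]) / r$dt, 1e-3)  # mV/ms
  expect_equal(v[n], -72.0771, tolerance = 1e-4)
  r3 <- simulate_network(network_model(list(make_three_compartment_trn())),
                         simulation_config(1000))
  v3 <- voltage_trace(r3, 1, "S")
  expect_lt(abs(v3[length(v3)] - v3[length(v3) - 1]) / r3$dt, 1e-3)
  expect_equal(v3[length(v3)], -76.0269, tolerance = 1e-4)
})

test_that("somatic depolarizing steps evoke spikes in the soma only", {
  m <- network_model(list(make_three_compartment_trn()),
                     injections = list(step_current(1, "S", 3, 100, 400)))
  r <- simulate_network(m, simulation_config(600))
  expect_gt(length(detect_spikes(r, cell = 1, comp = "S")), 0)
  # dendrites follow passively: no overshooting dendritic spikes
  expect_lt(max(voltage_trace(r, 1, "D")), 0)
})
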