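test_that("junctional currents follow the directional conductances", {
  s <- electrical_synapse(1, "S", 2, "S", g_ab = 0.15)
  expect_equal(gj_currents(s, -60, -60), c(into_a = 0, into_b = 0))
  # reference conductance, 10 mV difference
  i <- gj_currents(s, -70, -60)  # v_a - v_b = -10
  expect_equal(i[["into_b"]], -1.5)
  expect_equal(i[["into_a"]], 1.5)
  # linearity under doubled one-way conductance
  s2 <- electrical_synapse(1, "S", 2, "S", g_ab = 0.3, g_ba = 0.15)
  for (dv in c(-12, 3, 25)) {
    i2 <- gj_currents(s2, -60 + dv, -60)
    expect_equal(i2[["into_b"]], -2 * i2[["into_a"]])
  }
})

test_that("symmetric junctions conserve charge; asymmetric imbalance is (g_ab - g_ba)(v_a - v_b)", {
  sym <- electrical_synapse(1, "S", 2, "S", g_ab = 0.12)
  asym <- electrical_synapse(1, "S", 2, "S", g_ab = 0.2, g_ba = 0.05)
  for (va in c(-80, -65)) for (vb in c(-70, -55)) {
    expect_equal(sum(gj_currents(sym, va, vb)), 0)
    expect_equal(sum(gj_currents(asym, va, vb)), (0.2 - 0.05) * (va - vb))
  }
})

test_that("event trains validate ordering and round-trip through CSV", {
  expect_error(event_train(c(5, 5, 10)), "increasing")
  ev <- event_train(c(0, 5, 10), c(1, 2, 0.5))
  path <- tempfile(fileext = ".csv")
  write_event_train(ev, path)
  expect_equal(read_event_train(path), ev)
  unlink(path)
})

test_that("synaptic waveform is causal and peak-normalized", {
  syn <- chemical_synapse(1, "D", event_train(100), tau_rise = 5,
                          tau_fall = 35)
  expect_equal(syn_conductance(syn, c(0, 50, 99.99)), c(0, 0, 0))
  # peak of a unit event equals 1, at t_peak = tr*tf/(tf-tr)*log(tf/tr)
  tp <- 5 * 35 / 30 * log(7)
  expect_equal(syn_conductance(syn, 100 + tp), 1)
  expect_lt(syn_conductance(syn, 100 + tp + 1), 1)
  expect_lt(syn_conductance(syn, 100 + tp - 1), 1)
  # superposition of two events
  syn2 <- chemical_synapse(1, "D", event_train(c(100, 105)))
  expect_equal(syn_conductance(syn2, 112),
               syn_conductance(syn, 112) +
                 syn_conductance(chemical_synapse(1, "D", event_train(105)),
                                 112))
})

test_that("kinetic constraints on the chemical synapse are enforced", {
  expect_error(chemical_synapse(1, "D", event_train(0), tau_rise = 35,
                                tau_fall = 5))
  expect_silent(chemical_synapse(1, "D", event_train(0)))
})

test_that("distal EPSP amplitude grows sublinearly above 2 uA", {
  cell <- make_three_compartment_trn()
  epsp <- vapply(1:4, function(amp) {
    syn <- chemical_synapse(1, "D", event_train(50, amp))
    m <- network_model(list(cell), chemical = list(syn))
    r <- simulate_network(m, simulation_config(150))
    v <- voltage_trace(r, 1, "D")
    max(v) - v[1]
  }, numeric(1))
  gain <- diff(epsp)  # dEPSP per added uA
  expect_true(all(diff(gain) < 0))
  expect_lt(gain[3], gain[1])
})
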