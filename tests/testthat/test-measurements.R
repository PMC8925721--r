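test_that("uncoupled cells show exactly zero coupling", {
  cc <- measure_coupling(coupled_pair(c("S", "S"), 0), direction = "12")
  expect_identical(cc$cc_12, 0)
})

test_that("soma-measured coupling is ordered S-S > M-M > D-D", {
  ccs <- vapply(list(c("S", "S"), c("M", "M"), c("D", "D")), function(loc)
    measure_coupling(coupled_pair(loc, 0.15), direction = "12")$cc_12,
    numeric(1))
  expect_true(all(diff(ccs) < 0))
  # single-compartment pair couples more strongly than any of them
  single <- make_single_compartment_trn()
  cc1 <- measure_coupling(coupled_pair(c("S", "S"), 0.15, cell1 = single,
                                       cell2 = single),
                          direction = "12")$cc_12
  expect_gt(cc1, ccs[1])
})

test_that("a distal-distal junction couples dendrites more than somas", {
  m <- coupled_pair(c("D", "D"), 0.15)
  cc_soma <- measure_coupling(m, site = "S", direction = "12")$cc_12
  cc_dend <- measure_coupling(m, site = "D", direction = "12")$cc_12
  expect_gt(cc_dend, cc_soma)
})

test_that("spike contamination during the pulse is an error", {
  # a depolarizing co-injection makes cell 1 fire during the window
  m <- coupled_pair(c("S", "S"), 0.15,
                    injections = list(step_current(1, "S", 3, 300, 200)))
  expect_error(measure_coupling(m, direction = "12"), "spike contamination")
})

test_that("input resistance of a passive compartment is 1/g_leak", {
  expect_equal(measure_input_resistance(passive_single(), settle = 0), 10,
               tolerance = 1e-6)
  expect_equal(measure_input_resistance(passive_single(0.05), settle = 0),
               20, tolerance = 1e-6)
})

test_that("R_in calibration round-trips within 0.1% and brackets the printed factors", {
  cell <- make_three_compartment_trn()
  expect_identical(calibrate_rin_change(cell, 0), 1)
  f <- calibrate_rin_change(cell, -20)
  r0 <- measure_input_resistance(cell)
  achieved <- 100 * (measure_input_resistance(scale_leak(cell, f)) / r0 - 1)
  expect_equal(achieved, -20, tolerance = 0.1 / 20)
  # -25% input resistance needs a leak factor near the printed 1.45
  f25 <- calibrate_rin_change(cell, -25, method = "analytic")
  expect_gt(f25, 1.3)
  expect_lt(f25, 1.6)
  # +25% comes from a factor near the printed 0.75 (asymmetric bracket)
  fup <- calibrate_rin_change(cell, 25, method = "analytic")
  expect_gt(fup, 0.7)
  expect_lt(fup, 0.85)
})

test_that("exchanging the two cells inverts the cc ratio exactly", {
  cell <- make_three_compartment_trn()
  cell2 <- scale_leak(cell, 1.2)
  a <- measure_coupling(coupled_pair(c("M", "D"), 0.15, cell1 = cell,
                                     cell2 = cell2))
  b <- measure_coupling(coupled_pair(c("D", "M"), 0.15, cell1 = cell2,
                                     cell2 = cell))
  expect_identical(a$cc_12, b$cc_21)
  expect_identical(a$cc_21, b$cc_12)
  expect_equal(a$cc_ratio, 1 / b$cc_ratio, tolerance = 1e-12)
})

test_that("latency protocol: uncoupled and zero-conductance references agree", {
  m0 <- coupled_pair(c("D", "D"), 0)
  lr <- measure_latency(m0, 250, 250)
  expect_equal(lr$latency_difference, 0)
  expect_equal(lr$latency_1, lr$latency_uncoupled)
  expect_equal(lr$latency_2, lr$latency_uncoupled)
  # with offset onsets but no coupling, each latency still equals uncoupled
  # (to within the slow relaxation of the held state between the two onsets)
  lr2 <- measure_latency(m0, 250, 270)
  expect_equal(lr2$latency_1, lr2$latency_uncoupled)
  expect_equal(lr2$latency_2, lr2$latency_uncoupled, tolerance = 1e-3)
})

test_that("latency sign convention is antisymmetric under mirror locations", {
  lu <- measure_latency(coupled_pair(c("S", "S"), 0), 250, 250)$latency_1
  a <- measure_latency(coupled_pair(c("D", "M"), 0.2), 250, 250,
                       latency_uncoupled = lu)
  b <- measure_latency(coupled_pair(c("M", "D"), 0.2), 250, 250,
                       latency_uncoupled = lu)
  expect_equal(a$latency_difference, -b$latency_difference)
  expect_gt(abs(a$latency_difference), 1)
})

test_that("fft cross-correlation matches the direct sum", {
  set.seed(42)
  f1 <- rnorm(400); f2 <- rnorm(400)
  cg <- gapasym:::cross_correlation(f1, f2, 25)
  expect_equal(cg$value, direct_xcorr(f1, f2, 25), tolerance = 1e-10)
  expect_equal(cg$lag, -25:25)
})

test_that("train phase: identical trains give 0, half-period shift gives 180", {
  sp1 <- seq(1000, 1480, by = 20)
  same <- train_phase(sp1, sp1, t0 = 1000, window = 500)
  expect_equal(same$phase, 0)
  shifted <- train_phase(sp1, sp1 + 10, t0 = 1000, window = 500, isi = 20)
  expect_equal(abs(shifted$phase), 180)
  quarter <- train_phase(sp1, sp1 + 5, t0 = 1000, window = 500, isi = 20)
  expect_equal(quarter$phase, 90, tolerance = 1)
  # positive phase = train 2 later; reversed shift flips the sign
  lead <- train_phase(sp1, sp1 - 5, t0 = 1000, window = 500, isi = 20)
  expect_equal(lead$phase, -90, tolerance = 1)
})

test_that("synchrony protocol reports locked identical cells at phase 0", {
  cell <- make_single_compartment_trn()
  m <- coupled_pair(c("S", "S"), 0.01, cell1 = cell, cell2 = cell,
                    injections = make_tonic_pair(0.6, 0.6))
  sy <- measure_synchrony(m)
  expect_true(sy$rate_converged)
  expect_equal(sy$isi_1, sy$isi_2, tolerance = 1e-6)
  expect_equal(sy$phase_difference, 0, tolerance = 1)
  # identical drives, identical cells: exact synchrony by symmetry
  expect_equal(sy$t_max_lag, 0)
})

test_that("correlogram normalization does not move the measured phase", {
  cell <- make_single_compartment_trn()
  m <- coupled_pair(c("S", "S"), 0.025, cell1 = cell, cell2 = cell,
                    injections = make_tonic_pair())
  raw <- measure_synchrony(m)
  pea <- measure_synchrony(m, normalize = "pearson")
  expect_equal(raw$phase_difference, pea$phase_difference)
})
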