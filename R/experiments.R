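## Sweep runners regenerating the coupling, masking, latency and synchrony
## parameter maps as tidy tables. Every row echoes the full parameter tuple
## that produced it, and every runner is deterministic: re-running any grid
## cell reproduces its row bit-identically.

ALL_LOCATIONS <- as.matrix(expand.grid(loc_1 = c("S", "M", "D"),
                                       loc_2 = c("S", "M", "D"),
                                       stringsAsFactors = FALSE))

#' Coupling map over matched synapse locations (plus single-compartment pair)
#'
#' Symmetric gap junctions between matched compartments (S-S, M-M, D-D) of
#' identical three-compartment cells, and between two single-compartment
#' cells for comparison, measured either between somas or between distal
#' dendrites.
#'
#' @param g_c vector of symmetric junction conductances (mS/cm2).
#' @param site measurement/injection compartment ("S" or "D"; the
#'   single-compartment pair only supports "S").
#' @param passive zero all channels (for oracle cross-checks).
#' @param dt integration step (ms).
#' @return data.frame with one row per (configuration, g_c).
#' @export
run_cc_map <- function(g_c = seq(0.05, 0.25, by = 0.05), site = "S",
                       passive = FALSE, dt = 0.01) {
  cell3 <- make_three_compartment_trn()
  cell1 <- make_single_compartment_trn()
  if (passive) { cell3 <- zero_channels(cell3); cell1 <- zero_channels(cell1) }
  settle <- if (passive) 0 else 500
  configs <- list(list(id = "S-S", loc = c("S", "S"), cell = cell3),
                  list(id = "M-M", loc = c("M", "M"), cell = cell3),
                  list(id = "D-D", loc = c("D", "D"), cell = cell3),
                  list(id = "single", loc = c("S", "S"), cell = cell1))
  rows <- list()
  for (cf in configs) {
    if (cf$id == "single" && site != "S") next
    for (g in g_c) {
      m <- coupled_pair(cf$loc, g_12 = g, cell1 = cf$cell, cell2 = cf$cell)
      cc <- measure_coupling(m, site = site, dt = dt, settle = settle)
      rows[[length(rows) + 1]] <-
        data.frame(config = cf$id, site = site, g_c = g,
                   cc_12 = cc$cc_12, cc_21 = cc$cc_21,
                   cc_ratio = cc$cc_ratio)
    }
  }
  do.call(rbind, rows)
}

#' Location-by-strength asymmetry grid
#'
#' Symmetric junctions at all 9 (cell-1 compartment, cell-2 compartment)
#' location pairs over a grid of conductances; soma-measured coupling in
#' both directions plus the asymmetry ratio.
#'
#' @param g_c vector of junction conductances (mS/cm2).
#' @param locations matrix/data.frame with columns \code{loc_1},
#'   \code{loc_2}; defaults to all 9 pairs.
#' @param passive,dt see \code{\link{run_cc_map}}.
#' @return data.frame with columns loc_1, loc_2, g_c, cc_12, cc_21, cc_ratio.
#' @export
run_location_grid <- function(g_c = seq(0.05, 0.25, by = 0.05),
                              locations = ALL_LOCATIONS,
                              passive = FALSE, dt = 0.01) {
  locations <- as.matrix(locations)
  cell <- make_three_compartment_trn()
  if (passive) cell <- zero_channels(cell)
  settle <- if (passive) 0 else 500
  rows <- list()
  for (r in seq_len(nrow(locations))) for (g in g_c) {
    m <- coupled_pair(c(locations[r, 1], locations[r, 2]), g_12 = g,
                      cell1 = cell, cell2 = cell)
    cc <- measure_coupling(m, dt = dt, settle = settle)
    rows[[length(rows) + 1]] <-
      data.frame(loc_1 = locations[r, 1], loc_2 = locations[r, 2], g_c = g,
                 cc_12 = cc$cc_12, cc_21 = cc$cc_21, cc_ratio = cc$cc_ratio)
  }
  do.call(rbind, rows)
}

#' Input-resistance-by-location asymmetry sweep
#'
#' Cell 2's input resistance is changed by calibrated leak scaling while
#' cell 1 is unchanged; coupling is measured for each location pair and
#' junction strength.
#'
#' @param rin_changes percentage changes of cell 2's input resistance.
#' @param g_c junction conductances (mS/cm2).
#' @param locations location pairs (see \code{\link{run_location_grid}}).
#' @param passive,dt see \code{\link{run_cc_map}}.
#' @return data.frame with the leak factor echoed per row.
#' @export
run_rin_sweep <- function(rin_changes = seq(-25, 25, by = 12.5),
                          g_c = c(0.1, 0.15, 0.2),
                          locations = ALL_LOCATIONS,
                          passive = FALSE, dt = 0.01) {
  locations <- as.matrix(locations)
  cell <- make_three_compartment_trn()
  if (passive) cell <- zero_channels(cell)
  settle <- if (passive) 0 else 500
  method <- if (passive) "analytic" else "simulate"
  factors <- vapply(rin_changes, function(p)
    calibrate_rin_change(cell, p, method = method, dt = dt), numeric(1))
  rows <- list()
  for (k in seq_along(rin_changes)) {
    cell2 <- scale_leak(cell, factors[k])
    for (r in seq_len(nrow(locations))) for (g in g_c) {
      m <- coupled_pair(c(locations[r, 1], locations[r, 2]), g_12 = g,
                        cell1 = cell, cell2 = cell2)
      cc <- measure_coupling(m, dt = dt, settle = settle)
      rows[[length(rows) + 1]] <-
        data.frame(loc_1 = locations[r, 1], loc_2 = locations[r, 2],
                   g_c = g, rin_change_pct = rin_changes[k],
                   leak_factor = factors[k],
                   cc_12 = cc$cc_12, cc_21 = cc$cc_21,
                   cc_ratio = cc$cc_ratio)
    }
  }
  do.call(rbind, rows)
}

#' Dendritic-geometry (internal conductance) sweep
#'
#' Cell 2's middle-soma and distal-middle internal conductances are scaled
#' over a grid; coupling asymmetry is measured per location pair.
#'
#' @param ms_factors,dm_factors scale factors for cell 2's internal
#'   conductances.
#' @param g_c junction conductance (mS/cm2).
#' @param locations location pairs.
#' @param passive,dt see \code{\link{run_cc_map}}.
#' @return data.frame of cc values over the grid.
#' @export
run_geometry_sweep <- function(ms_factors = seq(0.8, 1.2, by = 0.2),
                               dm_factors = seq(0.8, 1.2, by = 0.2),
                               g_c = 0.15, locations = ALL_LOCATIONS,
                               passive = FALSE, dt = 0.01) {
  locations <- as.matrix(locations)
  cell <- make_three_compartment_trn()
  if (passive) cell <- zero_channels(cell)
  settle <- if (passive) 0 else 500
  rows <- list()
  for (ms in ms_factors) for (dm in dm_factors) {
    cell2 <- scale_internal(cell, ms, dm)
    for (r in seq_len(nrow(locations))) for (g in g_c) {
      m <- coupled_pair(c(locations[r, 1], locations[r, 2]), g_12 = g,
                        cell1 = cell, cell2 = cell2)
      cc <- measure_coupling(m, dt = dt, settle = settle)
      rows[[length(rows) + 1]] <-
        data.frame(loc_1 = locations[r, 1], loc_2 = locations[r, 2],
                   g_c = g, ms_factor = ms, dm_factor = dm,
                   cc_12 = cc$cc_12, cc_21 = cc$cc_21,
                   cc_ratio = cc$cc_ratio)
    }
  }
  do.call(rbind, rows)
}

#' Directional-conductance (G_c ratio) by input-resistance sweep
#'
#' The junction couples the two somas; transmission from cell 2 to cell 1 is
#' held at \code{g_21} while the 1-to-2 conductance is scaled to the stated
#' ratios, and cell 2's input resistance is changed by calibrated leak
#' scaling.
#'
#' @param ratios G_c ratios \code{g_12/g_21}.
#' @param rin_changes percentage changes of cell 2's input resistance.
#' @param g_21 fixed 2-to-1 conductance (mS/cm2).
#' @param passive,dt see \code{\link{run_cc_map}}.
#' @return data.frame of cc values over the grid.
#' @export
run_gcratio_sweep <- function(ratios = c(0.3, 0.5, 0.667, 1, 1.5, 2, 3),
                              rin_changes = c(-20, -10, 0, 10, 20),
                              g_21 = 0.15, passive = FALSE, dt = 0.01) {
  cell <- make_three_compartment_trn()
  if (passive) cell <- zero_channels(cell)
  settle <- if (passive) 0 else 500
  method <- if (passive) "analytic" else "simulate"
  factors <- vapply(rin_changes, function(p)
    calibrate_rin_change(cell, p, method = method, dt = dt), numeric(1))
  rows <- list()
  for (k in seq_along(rin_changes)) {
    cell2 <- scale_leak(cell, factors[k])
    for (rt in ratios) {
      m <- coupled_pair(c("S", "S"), g_12 = g_21 * rt, g_21 = g_21,
                        cell1 = cell, cell2 = cell2)
      cc <- measure_coupling(m, dt = dt, settle = settle)
      rows[[length(rows) + 1]] <-
        data.frame(gc_ratio = rt, g_21 = g_21,
                   rin_change_pct = rin_changes[k], leak_factor = factors[k],
                   cc_12 = cc$cc_12, cc_21 = cc$cc_21,
                   cc_ratio = cc$cc_ratio)
    }
  }
  do.call(rbind, rows)
}

#' The six masking configurations
#'
#' Six parameter combinations in which independent sources of asymmetry
#' (directional junction conductance, input-resistance mismatch, synapse
#' location, dendritic geometry) combine to the same soma-measured asymmetry:
#' a coupling ratio of about 1.2 (configurations B, D, F: transmission
#' favouring cell 2) or about 0.8 (C, E, G: favouring cell 1).
#'
#' Configurations (junctions 0.15 mS/cm2, soma-soma unless stated):
#' B: G_c ratio 1.8, cell-2 R_in -20\%. C: G_c ratio 0.667, R_in +6\%.
#' D: M-D junction, R_in +25\%. E: M-S junction, R_in -12\%.
#' F: S-M junction, cell-2 internal conductances scaled (0.867, 0.8).
#' G: D-S junction, cell-2 internal conductances scaled (1.2, 1.2).
#'
#' @param passive zero all channels (oracle cross-checks).
#' @param dt integration step (ms).
#' @return data.frame with one row per configuration.
#' @export
run_masking_isoclines <- function(passive = FALSE, dt = 0.01) {
  cell <- make_three_compartment_trn()
  if (passive) cell <- zero_channels(cell)
  settle <- if (passive) 0 else 500
  method <- if (passive) "analytic" else "simulate"
  rin_cell <- function(p) scale_leak(cell, calibrate_rin_change(
    cell, p, method = method, dt = dt))
  configs <- list(
    B = list(loc = c("S", "S"), g_12 = 0.15 * 1.8, g_21 = 0.15,
             cell2 = rin_cell(-20)),
    C = list(loc = c("S", "S"), g_12 = 0.15 * 0.667, g_21 = 0.15,
             cell2 = rin_cell(6)),
    D = list(loc = c("M", "D"), g_12 = 0.15, g_21 = 0.15,
             cell2 = rin_cell(25)),
    E = list(loc = c("M", "S"), g_12 = 0.15, g_21 = 0.15,
             cell2 = rin_cell(-12)),
    F = list(loc = c("S", "M"), g_12 = 0.15, g_21 = 0.15,
             cell2 = scale_internal(cell, 0.867, 0.8)),
    G = list(loc = c("D", "S"), g_12 = 0.15, g_21 = 0.15,
             cell2 = scale_internal(cell, 1.2, 1.2)))
  rows <- lapply(names(configs), function(id) {
    cf <- configs[[id]]
    m <- coupled_pair(cf$loc, g_12 = cf$g_12, g_21 = cf$g_21,
                      cell1 = cell, cell2 = cf$cell2)
    cc <- measure_coupling(m, dt = dt, settle = settle)
    data.frame(config = id, loc_1 = cf$loc[1], loc_2 = cf$loc[2],
               g_12 = cf$g_12, g_21 = cf$g_21,
               cc_12 = cc$cc_12, cc_21 = cc$cc_21, cc_ratio = cc$cc_ratio)
  })
  do.call(rbind, rows)
}

#' Burst-latency modulation sweep
#'
#' For each junction location pair, conductance and burst-onset difference,
#' measures the between-cell difference in change-of-latency relative to the
#' uncoupled cell (see \code{\link{measure_latency}}). Rows where either
#' cell failed to spike are flagged with NA and excluded from summary
#' statistics by the caller.
#'
#' @param locations location pairs.
#' @param g_c junction conductances (mS/cm2).
#' @param onset_diffs burst onset differences t_in2 - t_in1 (ms).
#' @param base_onset onset of cell 1's burst (ms).
#' @param gc_ratio junction asymmetry \code{g_12/g_21} applied on top of
#'   \code{g_c} (taken as the 2-to-1 conductance).
#' @param dt integration step (ms).
#' @return data.frame with per-row latencies and latency difference.
#' @export
run_latency_sweep <- function(locations = ALL_LOCATIONS,
                              g_c = c(0.05, 0.1, 0.15, 0.2),
                              onset_diffs = seq(-30, 30, by = 2),
                              base_onset = 250, gc_ratio = 1, dt = 0.01) {
  locations <- as.matrix(locations)
  cell <- make_three_compartment_trn()
  # uncoupled latency is onset- and location-independent: compute once
  unc <- measure_latency(coupled_pair(c("S", "S"), g_12 = 0,
                                      cell1 = cell, cell2 = cell),
                         base_onset, base_onset, latency_uncoupled = NA,
                         dt = dt)
  lat_unc <- unc$latency_1
  rows <- list()
  for (r in seq_len(nrow(locations))) for (g in g_c) {
    m <- coupled_pair(c(locations[r, 1], locations[r, 2]),
                      g_12 = g * gc_ratio, g_21 = g,
                      cell1 = cell, cell2 = cell)
    for (dlt in onset_diffs) {
      lr <- measure_latency(m, base_onset, base_onset + dlt,
                            latency_uncoupled = lat_unc, dt = dt)
      rows[[length(rows) + 1]] <-
        data.frame(loc_1 = locations[r, 1], loc_2 = locations[r, 2],
                   g_c = g, gc_ratio = gc_ratio, onset_diff = dlt,
                   latency_1 = lr$latency_1, latency_2 = lr$latency_2,
                   latency_uncoupled = lat_unc,
                   latency_difference = lr$latency_difference)
    }
  }
  do.call(rbind, rows)
}

#' Synchrony phase map over junction strength and asymmetry
#'
#' Two single-compartment cells with tonic drives (0.575 and 0.6 uA/cm2 by
#' default); the 2-to-1 conductance takes the stated base strengths while
#' the 1-to-2 conductance is scaled to each asymmetry ratio.
#'
#' @param g_c_21 base (2-to-1) conductances (mS/cm2).
#' @param ratios asymmetry ratios \code{g_12/g_21}.
#' @param drives tonic drive amplitudes (uA/cm2).
#' @param duration,dt see \code{\link{measure_synchrony}}.
#' @return data.frame with ISIs, rate-convergence flag, peak lag and phase
#'   per grid cell.
#' @export
run_synchrony_map <- function(g_c_21 = c(0.005, 0.0125, 0.025),
                              ratios = c(0.3, 0.5, 0.75, 1, 1.5, 2, 3),
                              drives = c(0.575, 0.6),
                              duration = 2500, dt = 0.01) {
  cell <- make_single_compartment_trn()
  rows <- list()
  for (g in g_c_21) for (rt in ratios) {
    m <- coupled_pair(c("S", "S"), g_12 = g * rt, g_21 = g,
                      cell1 = cell, cell2 = cell,
                      injections = make_tonic_pair(drives[1], drives[2]))
    sy <- measure_synchrony(m, duration = duration, dt = dt)
    rows[[length(rows) + 1]] <-
      data.frame(g_c_21 = g, gc_ratio = rt, i1 = drives[1], i2 = drives[2],
                 isi_1 = sy$isi_1, isi_2 = sy$isi_2,
                 rate_converged = sy$rate_converged,
                 t_max_lag = sy$t_max_lag,
                 phase_difference = sy$phase_difference)
  }
  do.call(rbind, rows)
}

#' Symmetric-coupling synchrony sweep
#'
#' ISI convergence and phase as a symmetric junction is strengthened; used
#' to locate the coupling strength at which the two firing rates converge.
#'
#' @param g_c symmetric conductances (mS/cm2).
#' @inheritParams run_synchrony_map
#' @return data.frame as in \code{\link{run_synchrony_map}}.
#' @export
run_synchrony_sweep <- function(g_c = c(0.001, 0.002, 0.004, 0.008, 0.016,
                                        0.025),
                                drives = c(0.575, 0.6),
                                duration = 2500, dt = 0.01) {
  out <- lapply(g_c, function(g)
    run_synchrony_map(g_c_21 = g, ratios = 1, drives = drives,
                      duration = duration, dt = dt))
  do.call(rbind, out)
}

#' Cross-validate the integrator against the passive analytic oracle
#'
#' Runs passive (channel-free) versions of representative configurations
#' from the location, input-resistance, geometry, directional-conductance
#' and masking grids, and compares simulated coupling coefficients in both
#' directions with the closed-form nodal solution.
#'
#' @param dt integration step (ms).
#' @return data.frame with simulated and analytic cc values and their
#'   relative errors; the maximum relative error is the quantity gated in
#'   the test-suite.
#' @export
oracle_check <- function(dt = 0.01) {
  cell <- zero_channels(make_three_compartment_trn())
  configs <- list()
  add <- function(id, loc, g_12, g_21 = g_12, cell2 = cell) {
    configs[[length(configs) + 1]] <<- list(id = id, loc = loc, g_12 = g_12,
                                            g_21 = g_21, cell2 = cell2)
  }
  for (r in seq_len(nrow(ALL_LOCATIONS)))          # location grid
    for (g in c(0.05, 0.15, 0.25))
      add(paste0("loc:", ALL_LOCATIONS[r, 1], "-", ALL_LOCATIONS[r, 2],
                 "@", g), c(ALL_LOCATIONS[r, 1], ALL_LOCATIONS[r, 2]), g)
  for (p in c(-25, -12, 6, 25)) {                  # R_in mismatches
    f <- calibrate_rin_change(cell, p, method = "analytic")
    add(paste0("rin:", p), c("S", "S"), 0.15, cell2 = scale_leak(cell, f))
    add(paste0("rin:", p, ":MD"), c("M", "D"), 0.15,
        cell2 = scale_leak(cell, f))
  }
  for (fs in list(c(0.8, 0.8), c(0.867, 0.8), c(1.2, 1.2)))  # geometry
    add(paste0("geom:", fs[1], ",", fs[2]), c("S", "M"), 0.15,
        cell2 = scale_internal(cell, fs[1], fs[2]))
  for (rt in c(0.3, 0.667, 1.8, 3))                # directional conductance
    add(paste0("gcr:", rt), c("S", "S"), 0.15 * rt, 0.15)
  rows <- lapply(configs, function(cf) {
    m <- coupled_pair(cf$loc, g_12 = cf$g_12, g_21 = cf$g_21,
                      cell1 = cell, cell2 = cf$cell2)
    sim <- measure_coupling(m, dt = dt, settle = 0)
    an_12 <- analytic_cc(m, "12")
    an_21 <- analytic_cc(m, "21")
    data.frame(config = cf$id,
               cc_12_sim = sim$cc_12, cc_12_oracle = an_12,
               cc_21_sim = sim$cc_21, cc_21_oracle = an_21,
               rel_err_12 = abs(sim$cc_12 / an_12 - 1),
               rel_err_21 = abs(sim$cc_21 / an_21 - 1),
               ratio_rel_err = abs((sim$cc_12 / sim$cc_21) /
                                     (an_12 / an_21) - 1))
  })
  do.call(rbind, rows)
}
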