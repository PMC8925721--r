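## The three measurement protocols: coupling coefficients and asymmetry,
## burst-latency modulation, and tonic spike-train phase synchrony; plus the
## input-resistance protocol used to calibrate leak scaling.

#' Build a two-cell model coupled by one gap junction
#'
#' @param location length-2 character vector: compartment of cell 1 and of
#'   cell 2 hosting the junction, e.g. \code{c("S","M")} for a soma-to-middle
#'   synapse.
#' @param g_12 conductance governing transmission from cell 1 into cell 2
#'   (mS/cm2).
#' @param g_21 conductance for the reverse direction; defaults to \code{g_12}.
#' @param cell1,cell2 \code{cell_params}; default three-compartment TRN cells.
#' @param injections,chemical stimuli forwarded to \code{network_model}.
#' @return two-cell \code{network_model}.
#' @export
coupled_pair <- function(location = c("S", "S"), g_12 = 0.15, g_21 = g_12,
                         cell1 = make_three_compartment_trn(),
                         cell2 = cell1,
                         injections = list(), chemical = list()) {
  stopifnot(length(location) == 2)
  syn <- electrical_synapse(1, location[1], 2, location[2],
                            g_ab = g_12, g_ba = g_21)
  network_model(list(cell1, cell2), electrical = list(syn),
                chemical = chemical, injections = injections)
}

## steady-state deflection: mean over last `window` ms of the pulse minus
## mean over the `window` ms immediately preceding pulse onset
steady_deflection <- function(trace, time, onset, pulse_ms, window = 200) {
  base <- trace[time >= onset - window & time < onset]
  stim <- trace[time >= onset + pulse_ms - window & time < onset + pulse_ms]
  mean(stim) - mean(base)
}

#' Measure coupling coefficients of a coupled pair
#'
#' The experimental protocol: a 500-ms hyperpolarizing square current into
#' one cell; the steady-state deflection is the mean voltage over the last
#' 200 ms of the pulse relative to a 200-ms pre-pulse baseline, read at the
#' stated site in both cells; \code{cc = dV_other / dV_injected}. Both
#' directions are measured in separate runs and combined into the asymmetry
#' ratio \code{cc_12/cc_21}.
#'
#' @param model two-cell \code{network_model} (stimulus-free; the pulse is
#'   added internally).
#' @param direction "both" (default), "12" or "21".
#' @param site compartment for injection and recording ("S" or "D").
#' @param inject_site,record_site optional overrides of \code{site}.
#' @param amplitude pulse amplitude (uA/cm2, negative).
#' @param onset pulse onset (ms); must leave room for the 200-ms baseline.
#' @param pulse_ms pulse duration (ms).
#' @param dt,settle integration step and settling time (ms). Settling may be
#'   0 for passive models, which start exactly at rest.
#' @return object of class \code{coupling_measurement}: \code{cc_12},
#'   \code{cc_21}, \code{cc_ratio}, the deflections, and the sites. Errors
#'   if a spike contaminates the pulse window (the protocol is subthreshold).
#' @export
measure_coupling <- function(model, direction = c("both", "12", "21"),
                             site = "S", inject_site = site,
                             record_site = site,
                             amplitude = -0.5, onset = 200, pulse_ms = 500,
                             dt = 0.01, settle = 500) {
  direction <- match.arg(direction)
  stopifnot(inherits(model, "network_model"), length(model$cells) == 2,
            amplitude < 0)
  cfg <- simulation_config(duration = onset + pulse_ms + 100, dt = dt,
                           settle_time = settle)
  # unstimulated control run: subtracting it isolates the pulse response
  # from any residual slow relaxation toward rest, so the last-200-ms
  # steady-state estimator is unbiased even for small test pulses
  ctrl <- simulate_network(model, cfg)
  one <- function(src) {
    dst <- 3 - src
    m <- model
    m$injections <- c(m$injections,
                      list(step_current(src, inject_site, amplitude,
                                        onset = onset, duration = pulse_ms)))
    res <- simulate_network(m, cfg)
    for (ci in 1:2) {
      sp <- detect_spikes(res, cell = ci, comp = "S")
      if (any(sp >= onset & sp < onset + pulse_ms))
        stop("spike contamination during the coupling pulse (cell ", ci,
             "); the protocol requires subthreshold responses")
    }
    dv_src <- steady_deflection(voltage_trace(res, src, record_site) -
                                  voltage_trace(ctrl, src, record_site),
                                res$time, onset, pulse_ms)
    dv_dst <- steady_deflection(voltage_trace(res, dst, record_site) -
                                  voltage_trace(ctrl, dst, record_site),
                                res$time, onset, pulse_ms)
    c(injected = dv_src, coupled = dv_dst, cc = dv_dst / dv_src)
  }
  out <- list(cc_12 = NA_real_, cc_21 = NA_real_, cc_ratio = NA_real_,
              site = site, inject_site = inject_site,
              record_site = record_site)
  if (direction %in% c("both", "12")) {
    r <- one(1)
    out$cc_12 <- r[["cc"]]
    out$dV_injected_1 <- r[["injected"]]; out$dV_coupled_12 <- r[["coupled"]]
  }
  if (direction %in% c("both", "21")) {
    r <- one(2)
    out$cc_21 <- r[["cc"]]
    out$dV_injected_2 <- r[["injected"]]; out$dV_coupled_21 <- r[["coupled"]]
  }
  if (direction == "both") out$cc_ratio <- out$cc_12 / out$cc_21
  structure(out, class = "coupling_measurement")
}

#' @export
print.coupling_measurement <- function(x, ...) {
  cat(sprintf("<coupling: cc_12 = %.4f, cc_21 = %.4f, ratio = %.4f (site %s)>\n",
              x$cc_12, x$cc_21, x$cc_ratio, x$record_site))
  invisible(x)
}

#' Measure input resistance of a single cell
#'
#' Subthreshold hyperpolarizing step at the site; R_in = dV_steady / I using
#' the same last-200-ms steady-state convention as the coupling protocol.
#'
#' @param cell \code{cell_params}.
#' @param site compartment label.
#' @param amplitude test-pulse amplitude (uA/cm2, negative).
#' @param dt,settle integration parameters (ms).
#' @return input resistance (mV per uA/cm2).
#' @export
measure_input_resistance <- function(cell, site = "S", amplitude = -0.5,
                                     dt = 0.01, settle = 500) {
  stopifnot(inherits(cell, "cell_params"), amplitude < 0)
  onset <- 200; pulse_ms <- 500
  m0 <- network_model(list(cell))
  m <- network_model(list(cell),
                     injections = list(step_current(1, site, amplitude,
                                                    onset, pulse_ms)))
  cfg <- simulation_config(duration = onset + pulse_ms + 100, dt = dt,
                           settle_time = settle)
  res <- simulate_network(m, cfg)
  ctrl <- simulate_network(m0, cfg)  # see measure_coupling: drift control
  dv <- steady_deflection(voltage_trace(res, 1, site) -
                            voltage_trace(ctrl, 1, site),
                          res$time, onset, pulse_ms)
  dv / amplitude
}

#' Find the leak factor realising a target input-resistance change
#'
#' Bisection on \code{\link{scale_leak}} until the measured input resistance
#' differs from the unscaled cell's by the target percentage. The printed
#' leak bracket 0.75-1.45 maps asymmetrically onto roughly +/-25\% input
#' resistance, so the factor is calibrated rather than assumed linear.
#'
#' @param cell \code{cell_params}.
#' @param target_pct desired percentage change of R_in (within +/-25).
#' @param site measurement compartment.
#' @param tol convergence tolerance on the achieved change (percentage
#'   points).
#' @param method "simulate" measures R_in with the full active model;
#'   "analytic" uses the passive nodal solution (exact for passive sweeps,
#'   and much faster).
#' @param dt integration step for the simulated method (ms).
#' @return the leak scale factor.
#' @export
calibrate_rin_change <- function(cell, target_pct, site = "S", tol = 0.01,
                                 method = c("simulate", "analytic"),
                                 dt = 0.01) {
  method <- match.arg(method)
  stopifnot(abs(target_pct) <= 25.5)
  if (target_pct == 0) return(1)
  rin <- if (method == "analytic") {
    function(f) analytic_input_resistance(
      network_model(list(scale_leak(cell, f))), 1, site)
  } else {
    function(f) measure_input_resistance(scale_leak(cell, f), site, dt = dt)
  }
  r0 <- rin(1)
  fobj <- function(f) 100 * (rin(f) / r0 - 1) - target_pct
  lo <- 0.5; hi <- 2  # R_in decreases with factor: fobj(lo) > 0 > fobj(hi)
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    v <- fobj(mid)
    if (abs(v) < tol) return(mid)
    if (v > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Measure latency modulation under paired burst input
#'
#' Both cells receive the standard burst (13 EPSCs, 1 uA/cm2, 5-ms ISI, to
#' the distal dendrite, with 0.5 uA/cm2 somatic holding current); burst
#' onsets may differ. Latency is the time from a cell's own first EPSC to
#' its first somatic spike. The uncoupled reference latency comes from the
#' same cell with the junction conductances set to zero. The reported
#' modulation is \code{(lat_1 - lat_unc) - (lat_2 - lat_unc)}, i.e. change
#' of latency of cell 1 minus change of latency of cell 2.
#'
#' @param model two-cell \code{network_model} (three-compartment cells).
#' @param onset_1,onset_2 first-EPSC times (ms).
#' @param latency_uncoupled optional precomputed uncoupled latency (ms);
#'   when NULL it is simulated (junctions zeroed, same stimuli).
#' @param tail_ms post-burst simulation window for spike detection (ms).
#' @param dt,settle integration parameters (ms).
#' @param burst_args extra arguments forwarded to \code{\link{make_burst}}.
#' @return object of class \code{latency_result}: per-cell latencies,
#'   uncoupled latency, and \code{latency_difference}. Latencies are NA
#'   (flagged) when no spike occurs in the window.
#' @export
measure_latency <- function(model, onset_1, onset_2,
                            latency_uncoupled = NULL, tail_ms = 200,
                            dt = 0.01, settle = 500, burst_args = list()) {
  stopifnot(inherits(model, "network_model"), length(model$cells) == 2)
  bursts <- lapply(1:2, function(ci)
    do.call(make_burst, c(list(cell = ci,
                               onset = if (ci == 1) onset_1 else onset_2),
                          burst_args)))
  m <- model
  m$injections <- c(m$injections, lapply(bursts, `[[`, "holding"))
  m$chemical <- c(m$chemical, lapply(bursts, `[[`, "synapse"))
  dur <- max(onset_1, onset_2) + 60 + tail_ms
  cfg <- simulation_config(duration = dur, dt = dt, settle_time = settle)
  res <- simulate_network(m, cfg)
  lat <- function(result, ci, onset) {
    sp <- detect_spikes(result, cell = ci, comp = "S")
    sp <- sp[sp >= onset]
    if (!length(sp)) NA_real_ else sp[1] - onset
  }
  lat1 <- lat(res, 1, onset_1)
  lat2 <- lat(res, 2, onset_2)
  if (is.null(latency_uncoupled)) {
    mu <- m
    mu$electrical <- lapply(mu$electrical, function(s) {
      s$g_ab <- 0; s$g_ba <- 0; s
    })
    ru <- simulate_network(mu, cfg)
    latency_uncoupled <- lat(ru, 1, onset_1)
  }
  structure(list(latency_1 = lat1, latency_2 = lat2,
                 latency_uncoupled = latency_uncoupled,
                 latency_difference =
                   (lat1 - latency_uncoupled) - (lat2 - latency_uncoupled),
                 onset_1 = onset_1, onset_2 = onset_2),
            class = "latency_result")
}

#' @export
print.latency_result <- function(x, ...) {
  cat(sprintf("<latency: cell1 %.2f ms, cell2 %.2f ms, uncoupled %.2f ms, difference %.2f ms>\n",
              x$latency_1, x$latency_2, x$latency_uncoupled,
              x$latency_difference))
  invisible(x)
}

## raw linear cross-correlation C(k) = sum_t f1[t] * f2[t + k], |k| <= K.
## Positive peak lag means cell 2 fires after cell 1.
cross_correlation <- function(f1, f2, max_lag) {
  n <- length(f1)
  full <- stats::convolve(f2, f1, type = "open")  # length 2n - 1
  k <- -max_lag:max_lag
  vals <- full[n + k]
  data.frame(lag = k, value = vals)
}

#' Phase difference between two spike trains
#'
#' The correlogram stage of the synchrony protocol, usable on any pair of
#' spike trains: trains are binarized on a regular grid, filtered with a
#' Hanning window, cross-correlated, and the lag of the correlogram peak
#' nearest zero (ties broken toward non-negative lags) is converted to a
#' phase by \code{t_max_lag / isi * 360}, mapped to [-180, 180] degrees.
#' Positive phase means train 2 fires after train 1.
#'
#' @param spikes_1,spikes_2 spike times (ms) inside \code{[t0, t0 + window)}.
#' @param t0,window analysis window start and length (ms).
#' @param dt grid step (ms).
#' @param hanning_ms filter width (ms).
#' @param isi interspike interval for the phase formula (ms); defaults to
#'   the mean ISI of train 1.
#' @param normalize "raw" or "pearson" correlogram scaling.
#' @return list with \code{t_max_lag} (ms), \code{phase} (degrees), and the
#'   correlogram data.frame (\code{lag_ms}, \code{value}).
#' @export
train_phase <- function(spikes_1, spikes_2, t0, window, dt = 0.01,
                        hanning_ms = 5, isi = NULL,
                        normalize = c("raw", "pearson")) {
  normalize <- match.arg(normalize)
  if (is.null(isi)) isi <- mean(diff(spikes_1))
  nbin <- round(window / dt)
  binarize <- function(s) {
    x <- numeric(nbin)
    i <- round((s - t0) / dt) + 1
    x[i[i >= 1 & i <= nbin]] <- 1
    x
  }
  nw <- round(hanning_ms / dt) + 1
  w <- signal::hanning(nw)
  smooth <- function(x) {
    f <- stats::filter(x, w, sides = 2)
    f[is.na(f)] <- 0
    as.numeric(f)
  }
  f1 <- smooth(binarize(spikes_1))
  f2 <- smooth(binarize(spikes_2))
  K <- min(round(isi / dt), nbin - 1)
  cg <- cross_correlation(f1, f2, K)
  if (normalize == "pearson")
    cg$value <- cg$value / (stats::sd(f1) * stats::sd(f2) * length(f1))
  v <- cg$value
  peak <- which(diff(sign(diff(v))) < 0) + 1  # local maxima
  peak <- peak[v[peak] >= 0.5 * max(v)]
  if (!length(peak)) peak <- which.max(v)
  best <- peak[order(abs(cg$lag[peak]), -sign(cg$lag[peak]))][1]
  t_max_lag <- cg$lag[best] * dt
  phase <- t_max_lag / isi * 360
  phase <- ((phase + 180) %% 360) - 180
  if (phase == -180) phase <- 180
  list(t_max_lag = t_max_lag, phase = phase,
       cross_correlogram = data.frame(lag_ms = cg$lag * dt, value = cg$value))
}

#' Measure tonic spike-train synchrony and phase
#'
#' Somatic spike trains from a window of stable tonic firing are binarized
#' on the simulation grid, filtered with a 5-ms Hanning window, and
#' cross-correlated. The lag of the correlogram peak nearest zero, converted
#' by \code{phase = t_max_lag / ISI * 360}, gives the phase difference,
#' mapped to [-180, 180] degrees; positive phase means cell 2 fires after
#' cell 1. The ISI in the formula is the mean ISI of cell 1 over the window
#' (at phase-locked states the two ISIs agree, which is also reported).
#'
#' @param model two-cell \code{network_model} whose injections drive both
#'   cells to fire tonically.
#' @param window analysis window length (ms).
#' @param duration total simulated time (ms); the window is taken from the
#'   end of the run. If firing is non-stationary in the window (mean ISI
#'   drift above 5\% between its halves) the run is extended and the window
#'   shifted later, with a warning if stationarity is never reached.
#' @param dt,settle integration parameters (ms).
#' @param hanning_ms filter width (ms).
#' @param normalize "raw" (default) or "pearson" correlogram scaling; the
#'   peak lag, and hence the phase, is unaffected.
#' @return object of class \code{synchrony_metrics}: \code{isi_1},
#'   \code{isi_2}, \code{t_max_lag} (ms), \code{phase_difference} (degrees),
#'   \code{rate_converged} (are the two mean ISIs within 1\%?), and the
#'   correlogram as a data.frame.
#' @export
measure_synchrony <- function(model, window = 500, duration = 2500,
                              dt = 0.01, settle = 500, hanning_ms = 5,
                              normalize = c("raw", "pearson")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(model, "network_model"), length(model$cells) == 2)
  max_dur <- duration + 2000
  repeat {
    cfg <- simulation_config(duration = duration, dt = dt,
                             settle_time = settle)
    res <- simulate_network(model, cfg)
    t0 <- duration - window
    sp <- lapply(1:2, function(ci) {
      s <- detect_spikes(res, cell = ci, comp = "S")
      s[s >= t0 & s < duration]
    })
    if (any(vapply(sp, length, integer(1)) < 5))
      stop("fewer than 5 spikes in the analysis window; cells are not ",
           "firing tonically")
    drift <- vapply(sp, function(s) {
      isi <- diff(s)
      h <- length(isi) %/% 2
      abs(mean(isi[seq_len(h)]) - mean(isi[-seq_len(h)])) / mean(isi)
    }, numeric(1))
    if (all(drift <= 0.05) || duration >= max_dur) break
    duration <- duration + 500  # shift the window later
  }
  if (any(drift > 0.05))
    warning("firing still non-stationary (ISI drift ",
            sprintf("%.1f%%", 100 * max(drift)), ") at the final window")
  isi_1 <- mean(diff(sp[[1]]))
  isi_2 <- mean(diff(sp[[2]]))
  tp <- train_phase(sp[[1]], sp[[2]], t0 = t0, window = window, dt = dt,
                    hanning_ms = hanning_ms, isi = isi_1,
                    normalize = normalize)
  structure(list(isi_1 = isi_1, isi_2 = isi_2, t_max_lag = tp$t_max_lag,
                 phase_difference = tp$phase,
                 rate_converged = abs(isi_1 - isi_2) / isi_1 < 0.01,
                 cross_correlogram = tp$cross_correlogram),
            class = "synchrony_metrics")
}

#' @export
print.synchrony_metrics <- function(x, ...) {
  cat(sprintf("<synchrony: ISI %.2f / %.2f ms, peak lag %.2f ms, phase %.1f deg%s>\n",
              x$isi_1, x$isi_2, x$t_max_lag, x$phase_difference,
              if (x$rate_converged) ", rates converged" else ""))
  invisible(x)
}
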