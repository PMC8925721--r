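## Network assembly and the simulation front end.

#' Assemble a network model
#'
#' @param cells list of \code{cell_params}.
#' @param electrical list of \code{electrical_synapse}.
#' @param chemical list of \code{chemical_synapse}.
#' @param injections list of \code{stimulus} objects.
#' @return object of class \code{network_model}. Every synapse and stimulus
#'   endpoint is validated against the cells present.
#' @export
network_model <- function(cells, electrical = list(), chemical = list(),
                          injections = list()) {
  if (inherits(cells, "cell_params")) cells <- list(cells)
  stopifnot(all(vapply(cells, inherits, logical(1), "cell_params")))
  m <- structure(list(cells = cells, electrical = electrical,
                      chemical = chemical, injections = injections),
                 class = "network_model")
  check <- function(cell, comp, what) {
    if (cell < 1 || cell > length(cells))
      stop(what, " references missing cell ", cell)
    if (!comp %in% names(cells[[cell]]$compartments))
      stop(what, " references missing compartment ", cell, ".", comp)
  }
  for (s in electrical) {
    stopifnot(inherits(s, "electrical_synapse"))
    check(s$cell_a, s$comp_a, "electrical synapse")
    check(s$cell_b, s$comp_b, "electrical synapse")
  }
  for (s in chemical) {
    stopifnot(inherits(s, "chemical_synapse"))
    check(s$cell, s$comp, "chemical synapse")
  }
  for (s in injections) {
    stopifnot(inherits(s, "stimulus"))
    check(s$cell, s$comp, "injected current")
  }
  m
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model: %d cell(s), %d electrical, %d chemical synapse(s), %d injection(s)>\n",
              length(x$cells), length(x$electrical), length(x$chemical),
              length(x$injections)))
  invisible(x)
}

#' Simulation configuration
#'
#' @param duration simulated time after settling (ms).
#' @param dt integration step (ms); the 0.01-ms default passes the
#'   halve-the-step convergence check on all protocols used here.
#' @param settle_time pre-stimulus equilibration (ms). The system is
#'   integrated with all stimuli silenced for this long, so t = 0 starts from
#'   the resting state of the full model.
#' @param record_gates also record gating-variable trajectories.
#' @param seed integer seed; only consulted by randomized stimuli (none of
#'   the built-in protocols are random).
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(duration, dt = 0.01, settle_time = 500,
                              record_gates = FALSE, seed = NULL) {
  stopifnot(dt > 0, duration > 0, settle_time >= 0)
  structure(list(dt = dt, duration = duration, settle_time = settle_time,
                 record_gates = record_gates, seed = seed),
            class = "simulation_config")
}

## map (cell, comp) -> global compartment index; also flat parameter arrays
flatten_network <- function(model) {
  cells <- model$cells
  labels <- character(); cell_of <- integer()
  for (ci in seq_along(cells)) {
    labs <- names(cells[[ci]]$compartments)
    labels <- c(labels, labs)
    cell_of <- c(cell_of, rep(ci, length(labs)))
  }
  n <- length(labels)
  idx <- function(cell, comp) which(cell_of == cell & labels == comp)
  cm <- gleak <- eleak <- numeric(n)
  gmax <- erev <- matrix(0, nrow = length(CHANNEL_NAMES), ncol = n)
  rownames(gmax) <- rownames(erev) <- CHANNEL_NAMES
  erev[] <- DEFAULT_REVERSALS[CHANNEL_NAMES]
  k <- 0
  for (ci in seq_along(cells)) for (cp in cells[[ci]]$compartments) {
    k <- k + 1
    cm[k] <- cp$c_m; gleak[k] <- cp$g_leak; eleak[k] <- cp$e_leak
    for (ch in cp$channels) {
      gmax[ch$name, k] <- ch$g_max
      erev[ch$name, k] <- ch$e_rev
    }
  }
  ie <- matrix(0, 0, 3)
  for (ci in seq_along(cells)) {
    gi <- cells[[ci]]$g_internal
    labs <- names(cells[[ci]]$compartments)
    for (e in seq_along(gi))
      ie <- rbind(ie, c(idx(ci, labs[e]) - 1L, idx(ci, labs[e + 1]) - 1L,
                        gi[[e]]))
  }
  ge <- matrix(0, 0, 3)
  for (s in model$electrical) {
    ia <- idx(s$cell_a, s$comp_a); ib <- idx(s$cell_b, s$comp_b)
    ge <- rbind(ge, c(ib - 1L, ia - 1L, s$g_ab),  # into b, driven by V_a - V_b
                c(ia - 1L, ib - 1L, s$g_ba))
  }
  pu <- matrix(0, 0, 4)
  for (s in model$injections) {
    stim_end <- if (is.finite(s$duration)) s$onset + s$duration else Inf
    pu <- rbind(pu, c(idx(s$cell, s$comp) - 1L, s$onset, stim_end,
                      s$amplitude))
  }
  chem <- lapply(model$chemical, function(s) list(
    comp = idx(s$cell, s$comp) - 1L,
    mode = if (s$mode == "current") 0L else 1L,
    e_syn = s$e_syn, tau_rise = s$tau_rise, tau_fall = s$tau_fall,
    norm = s$norm, times = s$events$time_ms, amps = s$events$amplitude))
  list(n = n, labels = paste0("cell", cell_of, ".", labels),
       cm = cm, gleak = gleak, eleak = eleak, gmax = gmax, erev = erev,
       internal = ie, gj = ge, pulses = pu, chem = chem)
}

#' Integrate a network model
#'
#' Fixed-step midpoint (second-order Runge-Kutta) integration of the full
#' membrane equation: capacitive balance of leak, the six voltage-gated
#' currents, chemical synaptic drive, injected currents, gap-junctional
#' currents and internal compartment coupling. The run is deterministic
#' given (model, config). Integration starts \code{settle_time} ms before
#' t = 0; stimuli are silent before their onsets, so with the default
#' onsets (>= 0) the state at t = 0 is the model's rest (an onset of
#' \code{-Inf} marks a holding bias that is settled into).
#'
#' @param model \code{network_model}.
#' @param config \code{simulation_config}.
#' @return object of class \code{simulation_result}: \code{time} (ms, from 0
#'   to duration), \code{voltage} (matrix, one column per compartment, named
#'   \code{cell<i>.<label>}), optionally \code{gates}, plus the config.
#'   Aborts with a diagnostic naming the first offending compartment and
#'   time if any voltage exceeds 200 mV in magnitude.
#' @examples
#' cell <- make_single_compartment_trn()
#' m <- network_model(list(cell),
#'                    injections = list(step_current(1, "S", 2, 100, 200)))
#' res <- simulate_network(m, simulation_config(duration = 400))
#' @export
simulate_network <- function(model, config) {
  stopifnot(inherits(model, "network_model"),
            inherits(config, "simulation_config"))
  fl <- flatten_network(model)
  out <- sim_core(fl$cm, fl$gleak, fl$eleak, fl$gmax, fl$erev,
                  fl$internal, fl$gj, fl$pulses, fl$chem,
                  config$dt, config$duration, config$settle_time,
                  config$record_gates, 200)
  vm <- out$vm
  colnames(vm) <- fl$labels
  res <- list(time = seq(0, by = config$dt, length.out = nrow(vm)),
              voltage = vm, dt = config$dt, config = config,
              labels = fl$labels)
  if (config$record_gates) {
    gates <- out$gates
    colnames(gates) <- as.vector(outer(GATE_LABELS, fl$labels,
                                       function(g, l) paste(l, g, sep = ".")))
    res$gates <- gates
  }
  structure(res, class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result: %g ms at dt %g ms, %d compartment(s)>\n",
              max(x$time), x$dt, ncol(x$voltage)))
  rng <- apply(x$voltage, 2, range)
  for (j in seq_len(ncol(x$voltage)))
    cat(sprintf("  %s: V in [%.2f, %.2f] mV\n", colnames(x$voltage)[j],
                rng[1, j], rng[2, j]))
  invisible(x)
}

#' Extract one voltage trace
#' @param result \code{simulation_result}.
#' @param cell cell index.
#' @param comp compartment label.
#' @return numeric vector (mV), same length as \code{result$time}.
#' @export
voltage_trace <- function(result, cell, comp = "S") {
  col <- paste0("cell", cell, ".", comp)
  if (!col %in% colnames(result$voltage)) stop("no trace for ", col)
  result$voltage[, col]
}

#' Detect spikes in a voltage trace
#'
#' Upward threshold crossings, at most one spike per refractory window.
#' Model action potentials overshoot 0 mV robustly, so the count is
#' insensitive to thresholds over a wide band around the 0-mV default.
#'
#' @param trace voltage trace (mV) or a \code{simulation_result}.
#' @param dt sample interval (ms); taken from the result if one is given.
#' @param threshold spike threshold (mV).
#' @param refractory minimum spike separation (ms).
#' @param cell,comp trace selector when \code{trace} is a result.
#' @return spike times (ms, at the crossing sample); empty for subthreshold
#'   traces.
#' @export
detect_spikes <- function(trace, dt = NULL, threshold = 0, refractory = 2,
                          cell = 1, comp = "S") {
  if (inherits(trace, "simulation_result")) {
    dt <- trace$dt
    trace <- voltage_trace(trace, cell, comp)
  }
  stopifnot(is.numeric(trace), !is.null(dt))
  up <- which(trace[-1] >= threshold & trace[-length(trace)] < threshold)
  if (!length(up)) return(numeric(0))
  t <- up * dt  # crossing sample, time base starting at 0
  out <- t[1]; last <- t[1]
  for (ti in t[-1]) if (ti - last > refractory) {
    out <- c(out, ti); last <- ti
  }
  out
}

#' Write simulation traces as CSV
#'
#' Time plus one column per compartment; a JSON-style run manifest with the
#' full configuration echo is written alongside as \code{<path>.manifest}.
#' @param result \code{simulation_result}.
#' @param path output CSV path.
#' @export
write_traces_csv <- function(result, path) {
  d <- data.frame(time_ms = result$time, result$voltage, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  cfg <- result$config
  manifest <- sprintf(
    '{"dt": %g, "duration": %g, "settle_time": %g, "compartments": [%s]}',
    cfg$dt, cfg$duration, cfg$settle_time,
    paste0('"', result$labels, '"', collapse = ", "))
  writeLines(manifest, paste0(path, ".manifest"))
  invisible(path)
}

#' Plot voltage traces of a simulation
#'
#' Quick base-graphics view: one panel per cell, compartments overlaid.
#' @param x \code{simulation_result}.
#' @param cells which cells to draw (default: all).
#' @param ... passed to \code{matplot}.
#' @export
plot.simulation_result <- function(x, cells = NULL, ...) {
  cell_of <- sub("^cell(\\d+)\\..*$", "\\1", colnames(x$voltage))
  if (is.null(cells)) cells <- unique(cell_of)
  op <- graphics::par(mfrow = c(length(cells), 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  for (ci in cells) {
    v <- x$voltage[, cell_of == ci, drop = FALSE]
    graphics::matplot(x$time, v, type = "l", lty = 1,
                      xlab = "time (ms)", ylab = "V (mV)",
                      main = paste("cell", ci), ...)
    graphics::legend("topright", legend = colnames(v), bty = "n",
                     col = seq_len(ncol(v)), lty = 1, cex = 0.8)
  }
  invisible(x)
}
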