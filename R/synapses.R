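## Electrical synapses (gap junctions) with independent directional
## conductances, and AMPAergic chemical synapses driven by event trains.

#' Construct an electrical synapse
#'
#' A junction between two (cell, compartment) endpoints. Each direction has
#' its own conductance: \code{g_ab} governs transmission from endpoint a into
#' endpoint b (the current injected into b is \code{g_ab * (V_a - V_b)}), and
#' \code{g_ba} the reverse. Equal conductances give a symmetric junction;
#' their ratio \code{g_ab/g_ba} quantifies junctional asymmetry
#' (rectification in the extreme).
#'
#' @param cell_a,cell_b cell indices (1-based) of the two endpoints.
#' @param comp_a,comp_b compartment labels of the two endpoints.
#' @param g_ab conductance (mS/cm2) for transmission a -> b.
#' @param g_ba conductance (mS/cm2) for transmission b -> a; defaults to
#'   \code{g_ab} (symmetric junction).
#' @return object of class \code{electrical_synapse}.
#' @export
electrical_synapse <- function(cell_a, comp_a, cell_b, comp_b,
                               g_ab, g_ba = g_ab) {
  stopifnot(g_ab >= 0, g_ba >= 0)
  comp_a <- match.arg(comp_a, COMPARTMENT_LABELS)
  comp_b <- match.arg(comp_b, COMPARTMENT_LABELS)
  structure(list(cell_a = cell_a, comp_a = comp_a,
                 cell_b = cell_b, comp_b = comp_b,
                 g_ab = g_ab, g_ba = g_ba),
            class = "electrical_synapse")
}

#' @export
print.electrical_synapse <- function(x, ...) {
  cat(sprintf("<gap junction cell%d.%s <-> cell%d.%s: g_ab %g, g_ba %g mS/cm2%s>\n",
              x$cell_a, x$comp_a, x$cell_b, x$comp_b, x$g_ab, x$g_ba,
              if (x$g_ab == x$g_ba) " (symmetric)" else ""))
  invisible(x)
}

#' Instantaneous junctional currents
#'
#' @param syn \code{electrical_synapse}.
#' @param v_a,v_b membrane potentials (mV) at the two endpoints.
#' @return named vector: current into a (\code{g_ba*(v_b - v_a)}) and into b
#'   (\code{g_ab*(v_a - v_b)}), in uA/cm2. For a symmetric junction the two
#'   are equal and opposite (charge is conserved); an asymmetric junction
#'   leaves a net imbalance of \code{(g_ab - g_ba)*(v_a - v_b)}.
#' @export
gj_currents <- function(syn, v_a, v_b) {
  stopifnot(inherits(syn, "electrical_synapse"))
  c(into_a = syn$g_ba * (v_b - v_a), into_b = syn$g_ab * (v_a - v_b))
}

#' Construct an event train
#'
#' @param times onset times (ms), strictly increasing.
#' @param amplitudes per-event peak amplitude; recycled to length of
#'   \code{times}.
#' @return object of class \code{event_train} (data.frame with columns
#'   \code{time_ms}, \code{amplitude}).
#' @export
event_train <- function(times, amplitudes = 1) {
  stopifnot(is.numeric(times), all(is.finite(times)))
  if (is.unsorted(times, strictly = TRUE))
    stop("event times must be strictly increasing")
  amplitudes <- rep_len(amplitudes, length(times))
  structure(data.frame(time_ms = times, amplitude = amplitudes),
            class = c("event_train", "data.frame"))
}

#' Read / write an event train as two-column CSV
#' @param path CSV file with columns \code{time_ms}, \code{amplitude}.
#' @return \code{event_train}.
#' @export
read_event_train <- function(path) {
  d <- utils::read.csv(path)
  event_train(d$time_ms, d$amplitude)
}

#' @rdname read_event_train
#' @param events \code{event_train} to write.
#' @export
write_event_train <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Construct an AMPAergic chemical synapse
#'
#' Each event launches a difference-of-exponentials waveform
#' \code{exp(-t/tau_fall) - exp(-t/tau_rise)}, peak-normalized so that a
#' single event's waveform peaks at exactly its stated amplitude. By default
#' the waveform is injected as a current density (uA/cm2), matching
#' current-clamp "EPSC" drive; \code{mode = "conductance"} instead treats the
#' amplitude as a peak conductance density (mS/cm2) with driving force
#' \code{e_syn - V}.
#'
#' @param cell,comp target cell index and compartment label.
#' @param events an \code{event_train}.
#' @param e_syn synaptic reversal potential (mV); 0 for AMPA.
#' @param tau_rise,tau_fall rise and fall time constants (ms),
#'   \code{tau_fall > tau_rise > 0}.
#' @param mode "current" (default) or "conductance".
#' @return object of class \code{chemical_synapse}.
#' @export
chemical_synapse <- function(cell, comp, events, e_syn = 0,
                             tau_rise = 5, tau_fall = 35,
                             mode = c("current", "conductance")) {
  mode <- match.arg(mode)
  comp <- match.arg(comp, COMPARTMENT_LABELS)
  stopifnot(inherits(events, "event_train"), tau_rise > 0,
            tau_fall > tau_rise)
  structure(list(cell = cell, comp = comp, events = events, e_syn = e_syn,
                 tau_rise = tau_rise, tau_fall = tau_fall, mode = mode,
                 norm = syn_peak_norm(tau_rise, tau_fall)),
            class = "chemical_synapse")
}

## peak value of exp(-t/tau_f) - exp(-t/tau_r), used for normalization
syn_peak_norm <- function(tau_rise, tau_fall) {
  tp <- tau_rise * tau_fall / (tau_fall - tau_rise) * log(tau_fall / tau_rise)
  exp(-tp / tau_fall) - exp(-tp / tau_rise)
}

#' Evaluate the synaptic waveform at time t
#'
#' Sum over past events of the peak-normalized difference-of-exponentials
#' waveform; zero before the first event. Units are those of the event
#' amplitudes (uA/cm2 in "current" mode, mS/cm2 in "conductance" mode).
#'
#' @param syn \code{chemical_synapse}.
#' @param t time (ms), scalar or vector.
#' @return waveform value(s).
#' @export
syn_conductance <- function(syn, t) {
  stopifnot(inherits(syn, "chemical_synapse"), all(is.finite(t)))
  vapply(t, function(tt) {
    dtk <- tt - syn$events$time_ms
    use <- dtk >= 0
    sum(syn$events$amplitude[use] *
          (exp(-dtk[use] / syn$tau_fall) - exp(-dtk[use] / syn$tau_rise))) /
      syn$norm
  }, numeric(1))
}
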