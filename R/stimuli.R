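## Stimulus protocol generators. Every waveform is a pure function of its
## parameter tuple, so any experiment's stimulus set is reproducible from
## configuration alone.

#' Square current step
#'
#' @param cell,comp target cell index and compartment label.
#' @param amplitude current density (uA/cm2).
#' @param onset start time (ms, relative to the end of settling); \code{-Inf}
#'   makes the current active throughout settling (a holding bias).
#' @param duration pulse length (ms); \code{Inf} for a tonic drive.
#' @return object of class \code{stimulus} (kind "step").
#' @export
step_current <- function(cell, comp, amplitude, onset = 0, duration = Inf) {
  comp <- match.arg(comp, COMPARTMENT_LABELS)
  stopifnot(is.finite(amplitude), !is.nan(onset), onset < Inf,
            duration > 0)
  structure(list(kind = "step", cell = cell, comp = comp,
                 amplitude = amplitude, onset = onset, duration = duration),
            class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("<stimulus %s -> cell%d.%s: %g uA/cm2, onset %g ms, duration %g ms>\n",
              x$kind, x$cell, x$comp, x$amplitude, x$onset, x$duration))
  invisible(x)
}

#' Evaluate a step stimulus waveform
#' @param stim a step \code{stimulus}.
#' @param t time (ms), vector.
#' @return current density at each t.
#' @export
stim_waveform <- function(stim, t) {
  stopifnot(inherits(stim, "stimulus"), stim$kind == "step")
  ifelse(t >= stim$onset & t < stim$onset + stim$duration, stim$amplitude, 0)
}

#' Hyperpolarizing step for coupling-coefficient measurement
#'
#' A 500-ms square pulse delivered to the soma of one cell. The default
#' amplitude of -0.5 uA/cm2 sits well inside the subthreshold linear regime;
#' the measured coupling coefficient is amplitude-independent there (checked
#' by the linearity assertion in the test-suite).
#'
#' @param cell target cell index.
#' @param amplitude negative current density (uA/cm2).
#' @param onset pulse start (ms).
#' @param comp injection compartment (soma by default; distal injection is
#'   used for dendrite-to-dendrite coupling maps).
#' @return \code{stimulus}.
#' @export
make_cc_step <- function(cell, amplitude = -0.5, onset = 200, comp = "S") {
  if (amplitude > 0) stop("coupling-coefficient steps must be hyperpolarizing")
  step_current(cell, comp, amplitude, onset = onset, duration = 500)
}

#' Burst-like AMPAergic input with depolarizing holding current
#'
#' 13 EPSC events of 1 uA/cm2 peak amplitude at 5-ms inter-event interval,
#' delivered to the distal dendrite, plus a constant 0.5 uA/cm2 depolarizing
#' holding current to the soma that raises excitability.
#'
#' @param cell target cell index.
#' @param onset time of the first event (ms).
#' @param n_events,isi,amplitude burst geometry (events, ms, uA/cm2).
#' @param holding holding current density to the soma (uA/cm2).
#' @param holding_onset start of the holding current (ms); by default it is
#'   on from the beginning of settling, so the cell sits at its held steady
#'   state when the burst arrives.
#' @param mode passed to \code{\link{chemical_synapse}}.
#' @return list with elements \code{holding} (a \code{stimulus}) and
#'   \code{synapse} (a \code{chemical_synapse} whose \code{event_train} holds
#'   the burst).
#' @export
make_burst <- function(cell, onset, n_events = 13, isi = 5, amplitude = 1,
                       holding = 0.5, holding_onset = -Inf,
                       mode = "current") {
  stopifnot(n_events >= 1, isi > 0)
  ev <- event_train(onset + isi * (seq_len(n_events) - 1), amplitude)
  list(holding = step_current(cell, "S", holding, onset = holding_onset),
       synapse = chemical_synapse(cell, "D", ev, mode = mode))
}

#' Tonic drives for the two-cell synchrony protocol
#'
#' Constant somatic current to each of two single-compartment cells, with
#' cell 2 driven slightly harder so that its uncoupled firing rate is higher.
#'
#' @param i1,i2 drive amplitudes (uA/cm2); defaults 0.575 and 0.6.
#' @param onset drive start (ms).
#' @return list of two \code{stimulus} objects.
#' @export
make_tonic_pair <- function(i1 = 0.575, i2 = 0.6, onset = 0) {
  list(step_current(1, "S", i1, onset = onset),
       step_current(2, "S", i2, onset = onset))
}
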